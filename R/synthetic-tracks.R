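#' Parameters for synthetic run-and-reverse trajectories
#'
#' Cells move with a per-track speed drawn from a normal distribution,
#' reversing direction (180 degrees) at the events of a Poisson process and
#' wobbling by per-step Gaussian heading jitter, which emulates single-cell
#' motility recordings of surface-translocating rods.
#'
#' @param n_tracks Number of tracks.
#' @param duration_min Recording length, minutes (default 15).
#' @param frame_interval_s Sampling interval, seconds (default 30); must
#'   divide the duration.
#' @param speed_um_min `c(mean, sd)` of per-track speed, micrometres/minute.
#' @param reversal_rate_per_min Poisson reversal rate, events/minute.
#' @param heading_jitter_deg SD of per-step heading noise, degrees.
#' @param seed Integer seed.
#' @return A list of class `"track_params"`.
#' @export
track_params <- function(n_tracks = 30,
                         duration_min = 15,
                         frame_interval_s = 30,
                         speed_um_min = c(2, 0.5),
                         reversal_rate_per_min = 2 / 15,
                         heading_jitter_deg = 10,
                         seed = 1L) {
  check_mean_sd(speed_um_min, "speed_um_min")
  stopif_neg(reversal_rate_per_min, "reversal_rate_per_min")
  stopif_neg(heading_jitter_deg, "heading_jitter_deg")
  if (duration_min <= 0 || frame_interval_s <= 0) {
    stop("duration and frame interval must be > 0")
  }
  if (abs(duration_min * 60 / frame_interval_s -
          round(duration_min * 60 / frame_interval_s)) > 1e-9) {
    stop("'duration_min' must be divisible by 'frame_interval_s'")
  }
  structure(as.list(environment())[names(formals(track_params))],
            class = "track_params")
}

#' Generate run-and-reverse tracks with ground-truth reversal counts
#'
#' @param params A [track_params()] object.
#' @return A list: `tracks` (data.frame: `track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`), `truth` (data.frame: `track_id`, `n_reversals`, `speed_um_min`)
#'   and `params`.
#' @export
make_tracks <- function(params = track_params()) {
  stopifnot(inherits(params, "track_params"))
  with_seed(params$seed, {
    dt_min <- params$frame_interval_s / 60
    n_steps <- round(params$duration_min / dt_min)
    rows <- truth <- vector("list", params$n_tracks)
    for (i in seq_len(params$n_tracks)) {
      speed <- max(stats::rnorm(1, params$speed_um_min[1],
                                params$speed_um_min[2]), 0)
      # Poisson process of reversal times over the recording window
      n_rev <- stats::rpois(1, params$reversal_rate_per_min *
                              params$duration_min)
      rev_times <- sort(stats::runif(n_rev, 0, params$duration_min))
      heading <- stats::runif(1, 0, 2 * pi)
      pos <- matrix(0, n_steps + 1L, 2)
      pos[1, ] <- stats::runif(2, 0, 50)
      for (k in seq_len(n_steps)) {
        t0 <- (k - 1) * dt_min; t1 <- k * dt_min
        flips <- sum(rev_times > t0 & rev_times <= t1)
        if (flips %% 2 == 1) heading <- heading + pi
        step_heading <- heading +
          stats::rnorm(1, 0, params$heading_jitter_deg * pi / 180)
        pos[k + 1L, ] <- pos[k, ] +
          speed * dt_min * c(cos(step_heading), sin(step_heading))
      }
      rows[[i]] <- data.frame(
        track_id = i, frame = 0:n_steps,
        t_s = (0:n_steps) * params$frame_interval_s,
        x_um = pos[, 1], y_um = pos[, 2]
      )
      truth[[i]] <- data.frame(track_id = i, n_reversals = n_rev,
                               speed_um_min = speed)
    }
    list(tracks = do.call(rbind, rows), truth = do.call(rbind, truth),
         params = params)
  })
}
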