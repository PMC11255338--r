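#' Default timing distributions for division movies
#'
#' Reads the packaged fixtures config holding the `c(mean, sd)` (minutes,
#' normal truncated at zero) of the mid-cell cluster appearance offset and
#' lifetime and of the biosensor burst onset and duration.
#'
#' @param path Optional path to an alternative YAML config with the same keys.
#' @return Named list of `c(mean, sd)` vectors.
#' @export
timing_defaults <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "timing-defaults.yaml", package = "polburst")
    if (path == "") path <- file.path("inst", "extdata", "timing-defaults.yaml")
  }
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(x) c(x$mean, x$sd))
}

#' Parameters for a synthetic division movie
#'
#' One growing cell is followed through cytokinesis: the mother elongates,
#' splits abruptly into two labelled daughters at the completion frame
#' (t = 0), and the green channel carries the configured markers:
#'
#' * `"midcell_cluster"` — a bright cluster at the division site from
#'   `appearance offset` minutes before completion until completion
#'   (emulating a divisome-recruited enzyme fusion);
#' * `"biosensor"` — the whole-cell green/red ratio is elevated
#'   `burst_amplitude`-fold from `burst onset` before completion for
#'   `burst duration` minutes (emulating a ratiometric c-di-GMP sensor);
#' * `"polar_protein"` — clusters at the mother's old poles plus a released
#'   pool recruited to the division site late in cytokinesis and allocated
#'   to the daughters' new poles in proportion `daughter_allocation`.
#'
#' These correspond to distinct reporter strains, so the default renders
#' only the mid-cell cluster; pick the marker set per simulated experiment.
#'
#' @param frame_interval_min Minutes between frames.
#' @param doubling_time_min Population doubling time (bookkeeping; growth in
#'   the rendered window is linear).
#' @param cluster_appearance,burst_onset,burst_duration `c(mean, sd)` minutes
#'   of zero-truncated normals (defaults from [timing_defaults()]).
#' @param cluster_lifetime `NULL` (cluster disintegrates at completion, the
#'   default) or `c(mean, sd)` for an independently sampled lifetime.
#' @param burst_amplitude Fold-change of the green/red ratio during the burst.
#' @param daughter_allocation Fractions of the released polar pool given to
#'   each daughter; must sum to 1.
#' @param markers Character subset of
#'   `c("midcell_cluster", "biosensor", "polar_protein")`.
#' @param pre_span_min,post_span_min Minutes rendered before/after completion.
#' @param initial_length_um,cell_width_um,pixel_size_um Cell geometry.
#' @param green_base,red_base,background_intensity AU per pixel.
#' @param midcell_cluster_fluor,polar_cluster_fluor Total AU placed in the
#'   mid-cell cluster and in each old-pole cluster.
#' @param cluster_radius_px Radius of rendered cluster discs.
#' @param noise_gaussian_sd,poisson_scaling Camera noise model (see
#'   [scene_params()]).
#' @param gradual_constriction Narrow the mid-cell width over the last three
#'   mother frames instead of an abrupt split (stress-tests event detection).
#' @param randomize_orientation Random cell axis angle (default) or
#'   horizontal.
#' @param seed Integer seed.
#' @return A list of class `"movie_params"`.
#' @export
movie_params <- function(frame_interval_min = 5,
                         doubling_time_min = 300,
                         cluster_appearance = NULL,
                         cluster_lifetime = NULL,
                         burst_onset = NULL,
                         burst_duration = NULL,
                         burst_amplitude = 3,
                         daughter_allocation = c(0.5, 0.5),
                         markers = "midcell_cluster",
                         pre_span_min = 120,
                         post_span_min = 30,
                         initial_length_um = 3.5,
                         cell_width_um = 0.7,
                         pixel_size_um = 0.1,
                         green_base = 300,
                         red_base = 300,
                         background_intensity = 100,
                         midcell_cluster_fluor = 3e4,
                         polar_cluster_fluor = 2e4,
                         cluster_radius_px = 1.5,
                         noise_gaussian_sd = 5,
                         poisson_scaling = 1,
                         gradual_constriction = FALSE,
                         randomize_orientation = TRUE,
                         seed = 1L) {
  defaults <- timing_defaults()
  cluster_appearance <- cluster_appearance %||% defaults$cluster_appearance
  burst_onset <- burst_onset %||% defaults$burst_onset
  burst_duration <- burst_duration %||% defaults$burst_duration
  check_mean_sd(cluster_appearance, "cluster_appearance")
  check_mean_sd(burst_onset, "burst_onset")
  check_mean_sd(burst_duration, "burst_duration")
  if (!is.null(cluster_lifetime)) check_mean_sd(cluster_lifetime, "cluster_lifetime")
  if (frame_interval_min <= 0) stop("'frame_interval_min' must be > 0")
  if (length(daughter_allocation) != 2L || any(daughter_allocation < 0) ||
      abs(sum(daughter_allocation) - 1) > 1e-9) {
    stop("'daughter_allocation' must be two non-negative fractions summing to 1")
  }
  known <- c("midcell_cluster", "biosensor", "polar_protein")
  if (length(markers) && !all(markers %in% known)) {
    stop("unknown marker(s): ", paste(setdiff(markers, known), collapse = ", "))
  }
  if (burst_amplitude < 1) stop("'burst_amplitude' must be >= 1")
  structure(as.list(environment())[names(formals(movie_params))],
            class = "movie_params")
}

# Channel stack for one frame: cells as spherocylinders, markers on top.
render_movie_frame <- function(side, cells, params) {
  green <- matrix(0, side, side)
  red <- matrix(0, side, side)
  mask <- matrix(0L, side, side)
  for (cell in cells) {
    px <- cell$pixels
    lin <- px[, 1] + (px[, 2] - 1L) * side
    mask[lin] <- cell$label
    red[lin] <- red[lin] + params$red_base
    green[lin] <- green[lin] + params$green_base * cell$burst_factor
    for (cl in cell$clusters) {
      d2 <- (px[, 1] - cl$center[1])^2 + (px[, 2] - cl$center[2])^2
      disc <- which(d2 <= params$cluster_radius_px^2)
      if (length(disc)) {
        green[lin[disc]] <- green[lin[disc]] + cl$fluor / length(disc)
      }
    }
  }
  list(green = green, red = red, mask = mask)
}

#' Generate a synthetic division movie with ground truth
#'
#' Renders one cell lineage through cytokinesis at `frame_interval_min`
#' resolution. Frame times run from `-pre_span_min` to `+post_span_min`
#' relative to completion of cytokinesis, defined as the first frame in
#' which the two daughters are separated (two labels in the mask). Sampled
#' timing offsets are recorded in the truth table; marker windows are placed
#' in continuous time, so the rendered presence is quantized by the frame
#' grid exactly as a microscope would sample it.
#'
#' @param params A [movie_params()] object.
#' @return A list: `frames` (list of per-frame lists `green`, `red`, `mask`),
#'   `times_min` (frame times relative to completion), `completion_frame`
#'   (index of t = 0), `truth` (one-row data.frame with the sampled offsets,
#'   minutes) and `params`.
#' @export
make_division_movie <- function(params = movie_params()) {
  stopifnot(inherits(params, "movie_params"))
  with_seed(params$seed, {
    dt <- params$frame_interval_min
    pre_n <- floor(params$pre_span_min / dt)
    post_n <- floor(params$post_span_min / dt)
    times <- seq(-pre_n, post_n) * dt
    completion_frame <- pre_n + 1L

    px_per_um <- 1 / params$pixel_size_um
    L0 <- params$initial_length_um * px_per_um
    Lf <- 2 * L0
    wid <- params$cell_width_um * px_per_um
    side <- ceiling(Lf) + 14L
    ctr <- c(side / 2, side / 2)
    ang <- if (params$randomize_orientation) stats::runif(1, 0, pi) else 0
    u <- c(cos(ang), sin(ang))

    # Sampled event timings, minutes before completion. The configured
    # (mean, sd) describe the observable frame-aligned offsets, as a
    # time-lapse histogram reports them: the zero-truncated sampling
    # distribution is moment-matched to them and realized offsets snap to
    # the frame grid (minimum one frame, so every event carries its marker).
    max_off <- params$pre_span_min - 7 * dt
    draw_offset <- function(spec) {
      p <- match_truncnorm0(spec[1], spec[2])
      o <- rtruncnorm0(1, p[1], p[2])
      min(dt * max(1, round(o / dt)), max_off)
    }
    o_app <- draw_offset(params$cluster_appearance)
    o_b <- draw_offset(params$burst_onset)
    d_b <- draw_offset(params$burst_duration)
    lifetime <- if (is.null(params$cluster_lifetime)) Inf else
      draw_offset(params$cluster_lifetime)
    cluster_win <- c(-o_app, min(0, -o_app + lifetime))
    burst_win <- c(-o_b, -o_b + d_b)

    gap <- 2
    Ld <- (Lf - gap) / 2
    frames <- vector("list", length(times))
    for (i in seq_along(times)) {
      t <- times[i]
      in_burst <- "biosensor" %in% params$markers &&
        t >= burst_win[1] && t < burst_win[2]
      bf <- if (in_burst) params$burst_amplitude else 1
      if (t < 0) {
        L <- L0 + (Lf - L0) * (t - times[1]) / (0 - times[1])
        sc <- spherocylinder_pixels(ctr, ang, L, wid)
        px <- sc$pixels
        if (params$gradual_constriction && t >= -3 * dt) {
          # narrow the mid-cell width over the last three mother frames
          axial <- (px[, 1] - ctr[1]) * u[1] + (px[, 2] - ctr[2]) * u[2]
          radial <- abs((px[, 1] - ctr[1]) * -u[2] + (px[, 2] - ctr[2]) * u[1])
          shrink <- 1 - 0.25 * (4 + t / dt)  # 0.75, 0.5, 0.25
          drop <- abs(axial) <= 1.5 & radial > pmax(wid / 2 * shrink, 1)
          px <- px[!drop, , drop = FALSE]
        }
        ord <- order(px[, 2], px[, 1])
        px <- px[ord, , drop = FALSE]
        clusters <- list()
        if ("midcell_cluster" %in% params$markers &&
            t >= cluster_win[1] && t < cluster_win[2]) {
          clusters <- c(clusters, list(list(center = ctr,
                                            fluor = params$midcell_cluster_fluor)))
        }
        if ("polar_protein" %in% params$markers) {
          tips <- px[find_tips(px)$tips, , drop = FALSE]
          clusters <- c(clusters,
                        list(list(center = tips[1, ], fluor = params$polar_cluster_fluor),
                             list(center = tips[2, ], fluor = params$polar_cluster_fluor)))
          if (t >= cluster_win[1] && t < cluster_win[2]) {
            clusters <- c(clusters, list(list(center = ctr,
                                              fluor = 2 * params$polar_cluster_fluor)))
          }
        }
        cells <- list(list(label = 1L, pixels = px, clusters = clusters,
                           burst_factor = bf))
      } else {
        cells <- lapply(1:2, function(d) {
          sgn <- if (d == 1) -1 else 1
          dctr <- ctr + sgn * (Ld / 2 + gap / 2) * u
          sc <- spherocylinder_pixels(dctr, ang, Ld, wid)
          px <- sc$pixels
          ord <- order(px[, 2], px[, 1])
          px <- px[ord, , drop = FALSE]
          clusters <- list()
          if ("polar_protein" %in% params$markers) {
            tipidx <- find_tips(px)$tips
            tips <- px[tipidx, , drop = FALSE]
            # the new pole faces the division site (nearer the mother centre)
            dc <- (tips[, 1] - ctr[1])^2 + (tips[, 2] - ctr[2])^2
            new_tip <- tips[which.min(dc), ]
            old_tip <- tips[which.max(dc), ]
            clusters <- list(
              list(center = old_tip, fluor = params$polar_cluster_fluor),
              list(center = new_tip,
                   fluor = 2 * params$polar_cluster_fluor *
                     params$daughter_allocation[d])
            )
          }
          list(label = d + 1L, pixels = px, clusters = clusters,
               burst_factor = bf)
        })
      }
      fr <- render_movie_frame(side, cells, params)
      fr$green <- apply_camera_noise(fr$green + params$background_intensity,
                                     params$poisson_scaling,
                                     params$noise_gaussian_sd)
      fr$red <- apply_camera_noise(fr$red + params$background_intensity,
                                   params$poisson_scaling,
                                   params$noise_gaussian_sd)
      frames[[i]] <- fr
    }

    truth <- data.frame(
      completion_frame = completion_frame,
      cluster_appearance_min = o_app,
      cluster_lifetime_min = cluster_win[2] - cluster_win[1],
      burst_onset_min = o_b,
      burst_duration_min = d_b,
      allocation_1 = params$daughter_allocation[1],
      allocation_2 = params$daughter_allocation[2]
    )
    list(frames = frames, times_min = times,
         completion_frame = completion_frame, truth = truth, params = params)
  })
}
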