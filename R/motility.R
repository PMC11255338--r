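#' Mean speed of one track
#'
#' Mean frame-to-frame displacement divided by the frame interval. Tracks
#' must have strictly increasing, evenly spaced timestamps.
#'
#' @param track Data.frame with columns `t_s`, `x_um`, `y_um` (one track).
#' @return Speed in micrometres per minute.
#' @export
track_speed <- function(track) {
  track <- track[order(track$t_s), ]
  if (nrow(track) < 2L) stop("track needs at least 2 points")
  dts <- diff(track$t_s)
  if (any(dts <= 0) || max(abs(dts - dts[1])) > 1e-6) {
    stop("timestamps must be strictly increasing with constant spacing")
  }
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  mean(steps) / (dts[1] / 60)
}

# Smoothed step vectors: centred moving average of the displacement vectors
# over `window` steps (edges use the available part of the window).
smoothed_headings <- function(track, window = 3L) {
  dx <- diff(track$x_um); dy <- diff(track$y_um)
  n <- length(dx)
  half <- (window - 1L) %/% 2L
  sx <- sy <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    sx[i] <- mean(dx[j]); sy[i] <- mean(dy[j])
  }
  atan2(sy, sx)
}

ang_diff <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Count directional reversals in one track
#'
#' A candidate reversal is a step at which the heading changes by at least
#' `angle_threshold_deg` relative to the previous heading; candidate steps
#' closer together than `persistence_frames` merge into a single event, so
#' a brief back-and-forth excursion is scored once rather than twice. With
#' the default 120-degree threshold, per-step heading jitter of realistic
#' magnitude produces no false candidates without smoothing, and not
#' smoothing preserves genuine one-frame reversal runs; a moving-average
#' window (`smooth_window = 3`) is available for noisier data.
#'
#' @param track Data.frame with `t_s`, `x_um`, `y_um`.
#' @param angle_threshold_deg Minimal heading change (default 120).
#' @param persistence_frames Candidates closer than this merge (default 2).
#' @param smooth_window Moving-average window for step vectors (default 1,
#'   i.e. raw steps).
#' @return Integer reversal count.
#' @export
count_reversals <- function(track, angle_threshold_deg = 120,
                            persistence_frames = 2L, smooth_window = 1L) {
  th <- smoothed_headings(track, smooth_window)
  n <- length(th)
  if (n < 2L) return(0L)
  thr <- angle_threshold_deg * pi / 180
  cand <- which(ang_diff(th[-1], th[-n]) >= thr) + 1L
  if (!length(cand)) return(0L)
  # merge candidates separated by fewer than persistence_frames steps
  sum(diff(c(-Inf, cand)) >= persistence_frames)
}

#' Reversal-frequency distribution summaries by condition
#'
#' Histograms plus median +/- MAD per condition, and the pairwise MAD
#' ratios used to compare the breadth of reversal-frequency distributions
#' between genotypes.
#'
#' @param counts Named list of integer reversal-count vectors, one per
#'   condition.
#' @return A list: `summary` (data.frame: `condition`, `n`, `median`,
#'   `mad`), `histograms` (named list of tables) and `mad_ratio` (matrix of
#'   row/column MAD ratios).
#' @export
reversal_distribution <- function(counts) {
  if (!length(counts)) stop("need at least one condition")
  if (is.null(names(counts))) names(counts) <- paste0("cond", seq_along(counts))
  summ <- data.frame(
    condition = names(counts),
    n = vapply(counts, length, integer(1)),
    median = vapply(counts, stats::median, numeric(1)),
    mad = vapply(counts, mad_raw, numeric(1))
  )
  ratio <- outer(summ$mad, summ$mad, function(a, b) ifelse(b > 0, a / b, NA_real_))
  dimnames(ratio) <- list(summ$condition, summ$condition)
  list(summary = summ,
       histograms = lapply(counts, function(x) table(factor(x, 0:max(x, 1)))),
       mad_ratio = ratio)
}

#' Per-track speeds and reversal counts from a track table
#'
#' @param tracks Data.frame with `track_id`, `t_s`, `x_um`, `y_um`.
#' @param min_speed_um_min Tracks slower than this are flagged as
#'   not moving and excluded (only cells moving during the entire recording
#'   are informative for reversal statistics).
#' @param ... Passed to [count_reversals()].
#' @return Data.frame: `track_id`, `speed_um_min`, `n_reversals`, `moving`.
#' @export
analyze_tracks <- function(tracks, min_speed_um_min = 0.1, ...) {
  out <- lapply(split(tracks, tracks$track_id), function(tr) {
    sp <- track_speed(tr)
    data.frame(track_id = tr$track_id[1], speed_um_min = sp,
               n_reversals = count_reversals(tr, ...),
               moving = sp >= min_speed_um_min)
  })
  do.call(rbind, out)
}
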