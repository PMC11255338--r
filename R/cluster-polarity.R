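#' Detect polar fluorescence clusters in one cell
#'
#' A polar cluster is a connected set of pole-cap pixels whose intensity
#' exceeds the per-cell threshold `tau = mean(cytoplasm) + k_sd * SD(cytoplasm)`,
#' with at least `min_pixels` pixels and component mean at or above `tau`.
#' The SD is that of the cell's own cytoplasmic pixel intensities, so the
#' rule is self-contained per cell. By default only the largest qualifying
#' component per pole is reported, which keeps isolated noise speckles from
#' inflating pole totals; set `sum_components = TRUE` to sum all qualifying
#' components of a cap instead.
#'
#' @param cell A `cell_region` with poles assigned (see [find_poles()]).
#' @param image Intensity matrix.
#' @param k_sd Threshold multiplier (default 2; some low-contrast markers
#'   warrant 1.5).
#' @param min_pixels Minimum cluster size in pixels (default 3).
#' @param background Background level subtracted when reporting the
#'   cytoplasm-corrected cluster fluorescence.
#' @param sum_components Report the sum over all qualifying components per
#'   pole rather than the largest one.
#' @return A data.frame with zero, one or two rows and columns `pole`,
#'   `pixel_count`, `total_fluor` (raw sum), `corr_fluor` (sum above the
#'   cytoplasmic mean), `mean_fluor`.
#' @export
detect_polar_clusters <- function(cell, image, k_sd = 2, min_pixels = 3L,
                                  background = 0, sum_components = FALSE) {
  stopifnot(inherits(cell, "cell_region"))
  if (is.null(cell$pole_caps)) stop("call find_poles() first")
  if (k_sd <= 0) stop("'k_sd' must be > 0")
  cyto <- pixel_values(cell, image, cell$cytoplasm)
  if (length(cyto) == 0L) stop("cell has an empty cytoplasmic region")
  mu <- mean(cyto)
  tau <- mu + k_sd * stats::sd(cyto)
  if (is.na(tau)) tau <- mu  # single cytoplasm pixel

  rows <- list()
  for (pole in 1:2) {
    cap <- cell$pole_caps[[pole]]
    if (length(cap) == 0L) next
    vals <- pixel_values(cell, image, cap)
    # strictly above the cytoplasmic mean: with a flat cytoplasm (SD = 0)
    # pixels at the mean must not qualify, so a uniform cell yields no calls
    cand <- cap[vals >= tau & vals > mu]
    if (length(cand) == 0L) next
    comp <- label_components(cell$pixels[cand, , drop = FALSE])
    keep <- list()
    for (k in unique(comp)) {
      idx <- cand[comp == k]
      v <- pixel_values(cell, image, idx)
      if (length(idx) >= min_pixels && mean(v) >= tau) {
        keep[[length(keep) + 1L]] <- idx
      }
    }
    if (length(keep) == 0L) next
    if (!sum_components) {
      sizes <- lengths(keep)
      totals <- vapply(keep, function(i) sum(pixel_values(cell, image, i)),
                       numeric(1))
      best <- order(-sizes, -totals)[1]
      keep <- keep[best]
    }
    idx <- unlist(keep)
    v <- pixel_values(cell, image, idx)
    rows[[length(rows) + 1L]] <- data.frame(
      pole = pole, pixel_count = length(idx), total_fluor = sum(v),
      corr_fluor = sum(v - mu), mean_fluor = mean(v)
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(pole = integer(0), pixel_count = integer(0),
                      total_fluor = numeric(0), corr_fluor = numeric(0),
                      mean_fluor = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Asymmetry index of polar fluorescence
#'
#' `omega = (f1 - f2) / (f1 + f2)` where `f1` is the total fluorescence at
#' the brighter pole (pole 1) and `f2` at the other; a pole without a
#' detected cluster contributes 0. The index is 0 for perfectly symmetric
#' bipolar cells and 1 for unipolar cells, and is invariant to rescaling
#' both inputs by a common factor. Inputs may be given in either order.
#'
#' @param f1,f2 Non-negative polar fluorescence totals.
#' @return `omega` in `[0, 1]`, or `NA` if both inputs are zero (no polar
#'   signal; the caller records the cell as diffuse).
#' @export
asymmetry_index <- function(f1, f2) {
  if (any(c(f1, f2) < 0)) stop("polar fluorescence must be non-negative")
  hi <- pmax(f1, f2)
  lo <- pmin(f1, f2)
  ifelse(hi + lo > 0, (hi - lo) / (hi + lo), NA_real_)
}

#' Classify a polar localization pattern from omega
#'
#' Bins: unipolar (`omega > 0.9`), bipolar asymmetric
#' (`0.9 >= omega >= 0.2`, both boundaries inclusive), bipolar symmetric
#' (`omega < 0.2`). Cells with no detected polar signal (`omega = NA`) are
#' diffuse.
#'
#' @param omega Asymmetry index, or `NA` for no polar signal.
#' @return Character vector: `"unipolar"`, `"asymmetric"`, `"symmetric"` or
#'   `"diffuse"`.
#' @export
classify_pattern <- function(omega) {
  out <- ifelse(is.na(omega), "diffuse",
         ifelse(omega > 0.9, "unipolar",
         ifelse(omega >= 0.2, "asymmetric", "symmetric")))
  as.character(out)
}

#' Per-cell polarity record
#'
#' Runs cluster detection on one cell and condenses the calls into the
#' per-cell record used by all downstream summaries: total fluorescence at
#' pole 1 (the brighter pole) and pole 2, each pole's fraction of total
#' cellular fluorescence, omega and the pattern class.
#'
#' Cluster totals are corrected for the cytoplasmic level beneath the
#' cluster footprint (`corr_fluor`), so omega reflects the clustered signal
#' itself rather than the cluster's pixel area.
#'
#' @inheritParams detect_polar_clusters
#' @return One-row data.frame: `frame`, `label`, `pole1_fluor`,
#'   `pole2_fluor`, `frac1`, `frac2`, `omega`, `pattern`.
#' @export
polarity_record <- function(cell, image, k_sd = 2, min_pixels = 3L,
                            background = 0, sum_components = FALSE) {
  calls <- detect_polar_clusters(cell, image, k_sd = k_sd,
                                 min_pixels = min_pixels,
                                 background = background,
                                 sum_components = sum_components)
  pf <- c(0, 0)
  pf[calls$pole] <- pmax(calls$corr_fluor, 0)
  total <- sum(pixel_values(cell, image)) - background * cell$area_px
  f1 <- max(pf); f2 <- min(pf)
  omega <- if (nrow(calls) == 0L) NA_real_ else asymmetry_index(f1, f2)
  data.frame(
    frame = cell$frame, label = cell$label,
    pole1_fluor = f1, pole2_fluor = f2,
    frac1 = if (total > 0) f1 / total else NA_real_,
    frac2 = if (total > 0) f2 / total else NA_real_,
    omega = omega, pattern = classify_pattern(omega)
  )
}

#' Population summary of polarity records
#'
#' Median +/- MAD of the per-pole fluorescence fractions, pattern-class
#' fractions (diffuse reported separately), and the omega values of
#' non-diffuse cells (cells with no polar signal are excluded from the
#' omega distribution).
#'
#' @param records Data.frame of [polarity_record()] rows.
#' @return A list: `pole_stats` (data.frame with `pole`, `median_frac`,
#'   `mad_frac`), `pattern_fractions` (named numeric over all four classes),
#'   `omega` (numeric vector, non-diffuse cells only), `n_cells`.
#' @export
population_summary <- function(records) {
  if (nrow(records) == 0L) stop("need at least one record")
  nondiff <- records[records$pattern != "diffuse", , drop = FALSE]
  pole_stats <- data.frame(
    pole = 1:2,
    median_frac = c(stats::median(nondiff$frac1), stats::median(nondiff$frac2)),
    mad_frac = c(if (nrow(nondiff)) mad_raw(nondiff$frac1) else NA_real_,
                 if (nrow(nondiff)) mad_raw(nondiff$frac2) else NA_real_)
  )
  classes <- c("unipolar", "asymmetric", "symmetric", "diffuse")
  frac <- vapply(classes, function(cl) mean(records$pattern == cl), numeric(1))
  list(pole_stats = pole_stats, pattern_fractions = frac,
       omega = nondiff$omega, n_cells = nrow(records))
}

#' Quantify polar clusters in a snapshot image
#'
#' End-to-end convenience wrapper: builds cell regions from the mask,
#' estimates the background, finds poles, and returns one polarity record
#' per cell.
#'
#' @param image Intensity matrix.
#' @param mask Label matrix.
#' @param k_sd,min_pixels,sum_components Passed to [detect_polar_clusters()].
#' @param cap_depth_um,pixel_size_um Passed to [find_poles()].
#' @param min_area_px Minimum cell area in pixels.
#' @return Data.frame of per-cell polarity records.
#' @export
analyze_snapshot <- function(image, mask, k_sd = 2, min_pixels = 3L,
                             cap_depth_um = 0.35, pixel_size_um = 0.1,
                             min_area_px = 5L, sum_components = FALSE) {
  bg <- estimate_background(image, mask)
  cells <- cell_regions(mask, min_area_px = min_area_px)
  recs <- lapply(cells, function(cell) {
    cell <- find_poles(cell, cap_depth_um, pixel_size_um)
    polarity_record(cell, image, k_sd = k_sd, min_pixels = min_pixels,
                    background = bg, sum_components = sum_components)
  })
  do.call(rbind, recs)
}
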