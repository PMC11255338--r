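#' Link cell labels across frames and detect division events
#'
#' Frame-to-frame links are made by maximal pixel overlap: a label in frame
#' t+1 is linked to the frame-t label with which its intersection-over-union
#' (IoU) is largest, provided IoU >= `iou_min`. A parent with exactly two
#' linked children defines a division event whose completion frame (t = 0
#' for all offsets) is the child frame — the first frame in which the two
#' daughters are separated. Ambiguous many-to-many overlaps and parents
#' with more than two children are flagged and produce no event.
#'
#' @param masks List of integer label matrices, one per frame.
#' @param iou_min Minimum IoU for a link (default 0.2; a clean abrupt split
#'   gives each daughter an IoU of roughly 0.5 with its mother).
#' @return A list of class `"lineage"`: `edges` (data.frame of links with
#'   IoU), `events` (data.frame: `mother_label`, `completion_frame`,
#'   `daughter1`, `daughter2`), `flagged` (character vector of skipped
#'   ambiguities), `n_frames`.
#' @export
link_lineage <- function(masks, iou_min = 0.2) {
  if (length(masks) < 2L) stop("need at least 2 frames")
  edges <- list()
  flagged <- character(0)
  for (t in seq_len(length(masks) - 1L)) {
    m1 <- masks[[t]]; m2 <- masks[[t + 1L]]
    both <- m1 > 0 & m2 > 0
    if (!any(both)) next
    tab <- table(parent = m1[both], child = m2[both])
    a1 <- table(m1[m1 > 0]); a2 <- table(m2[m2 > 0])
    for (ci in colnames(tab)) {
      inter <- tab[, ci]
      iou <- as.numeric(inter) /
        (as.numeric(a1[rownames(tab)]) + as.numeric(a2[ci]) - as.numeric(inter))
      ok <- which(iou >= iou_min)
      if (length(ok) == 0L) next
      if (length(ok) > 1L) {
        flagged <- c(flagged, sprintf(
          "frame %d label %s: overlaps %d parents above iou_min", t + 1L,
          ci, length(ok)))
        next
      }
      edges[[length(edges) + 1L]] <- data.frame(
        frame_parent = t, label_parent = as.integer(rownames(tab)[ok]),
        frame_child = t + 1L, label_child = as.integer(ci), iou = iou[ok]
      )
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(frame_parent = integer(0), label_parent = integer(0),
               frame_child = integer(0), label_child = integer(0),
               iou = numeric(0))
  events <- list()
  if (nrow(edges)) {
    sp <- split(edges, list(edges$frame_parent, edges$label_parent), drop = TRUE)
    for (e in sp) {
      if (nrow(e) == 2L) {
        events[[length(events) + 1L]] <- data.frame(
          mother_label = e$label_parent[1],
          completion_frame = e$frame_child[1],
          daughter1 = min(e$label_child), daughter2 = max(e$label_child)
        )
      } else if (nrow(e) > 2L) {
        flagged <- c(flagged, sprintf(
          "frame %d label %d: %d children", e$frame_parent[1],
          e$label_parent[1], nrow(e)))
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(mother_label = integer(0), completion_frame = integer(0),
               daughter1 = integer(0), daughter2 = integer(0))
  structure(list(edges = edges, events = events, flagged = flagged,
                 n_frames = length(masks)),
            class = "lineage")
}

#' @export
print.lineage <- function(x, ...) {
  cat(sprintf("<lineage> %d frames, %d links, %d division events%s\n",
              x$n_frames, nrow(x$edges), nrow(x$events),
              if (length(x$flagged)) sprintf(", %d flagged", length(x$flagged))
              else ""))
  invisible(x)
}

# Interface pixels between the two daughters of an event: the pixels of each
# daughter that face the other across the division gap. The reach adapts to
# the realized gap width so the interface is never empty.
division_interface <- function(mask, event, reach = NULL) {
  p1 <- which(mask == event$daughter1, arr.ind = TRUE)
  p2 <- which(mask == event$daughter2, arr.ind = TRUE)
  if (nrow(p1) == 0L || nrow(p2) == 0L) stop("daughter labels not in mask")
  d2 <- outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2
  if (is.null(reach)) reach <- sqrt(min(d2)) + 1.5
  rbind(p1[apply(d2, 1, min) <= reach^2, , drop = FALSE],
        p2[apply(d2, 2, min) <= reach^2, , drop = FALSE])
}

#' Mid-cell cluster presence over a division event
#'
#' For each frame, the mid-zone is the set of cell pixels within
#' `cap_depth_um` of the constriction plane — the interface between the two
#' daughters, known retrospectively from their pixel sets at the completion
#' frame. Cluster presence uses the same rule as polar-cluster detection
#' with the mid-zone in place of a pole cap: threshold
#' `tau = mean + k_sd * SD` of the remaining (cytoplasmic) pixels, connected
#' candidate components of at least `min_pixels` pixels.
#'
#' @param event One row of `link_lineage()$events`.
#' @param masks List of label matrices.
#' @param green List of green-channel matrices.
#' @param k_sd,min_pixels Detection rule (see [detect_polar_clusters()]).
#' @param cap_depth_um,pixel_size_um Mid-zone half-width.
#' @return Logical vector of per-frame presence (same length as `masks`).
#' @export
midcell_cluster_series <- function(event, masks, green, k_sd = 2,
                                   min_pixels = 3L, cap_depth_um = 0.35,
                                   pixel_size_um = 0.1) {
  iface <- division_interface(masks[[event$completion_frame]], event)
  depth_px <- cap_depth_um / pixel_size_um
  present <- logical(length(masks))
  for (t in seq_along(masks)) {
    mask <- masks[[t]]
    px <- if (t < event$completion_frame) {
      which(mask == event$mother_label, arr.ind = TRUE)
    } else {
      which(mask == event$daughter1 | mask == event$daughter2, arr.ind = TRUE)
    }
    if (nrow(px) == 0L) next
    d2 <- outer(px[, 1], iface[, 1], "-")^2 + outer(px[, 2], iface[, 2], "-")^2
    in_zone <- apply(d2, 1, min) <= depth_px^2
    if (!any(in_zone) || all(in_zone)) next
    vals <- green[[t]][px]
    cyto <- vals[!in_zone]
    mu <- mean(cyto)
    tau <- mu + k_sd * stats::sd(cyto)
    if (is.na(tau)) next
    cand <- which(in_zone & vals >= tau & vals > mu)
    if (length(cand) < min_pixels) next
    comp <- label_components(as_pixel_matrix(px[cand, , drop = FALSE]))
    sizes <- tabulate(comp)
    present[t] <- any(vapply(which(sizes >= min_pixels), function(k) {
      mean(vals[cand[comp == k]]) >= tau
    }, logical(1)))
  }
  present
}

# Principal run of a logical series: the longest contiguous TRUE run, ties
# resolved to the latest (the event-associated signal brackets completion,
# while sporadic single-frame noise detections sit anywhere in the series).
principal_run <- function(x) {
  if (!any(x)) return(NULL)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hi <- which(r$values)
  best <- hi[r$lengths[hi] == max(r$lengths[hi])]
  best <- best[length(best)]
  c(start = starts[best], length = r$lengths[best])
}

#' Cluster appearance offset and lifetime from a presence series
#'
#' Timing is read off the principal presence run — the longest contiguous
#' run of present frames (ties resolved to the latest), which makes the
#' estimate robust to isolated single-frame noise detections. Appearance
#' offset is `(completion frame - run start frame) * frame_interval`;
#' lifetime is the run length times the frame interval. Runs may extend
#' past completion (e.g. when cytokinesis is blocked).
#'
#' @param presence Logical per-frame vector (see [midcell_cluster_series()]).
#' @param completion_frame Index of the first frame with separated daughters.
#' @param frame_interval Minutes per frame.
#' @return Named numeric: `appearance_offset_min`, `lifetime_min`; both `NA`
#'   if the cluster is never present.
#' @export
cluster_timing <- function(presence, completion_frame, frame_interval) {
  run <- principal_run(presence)
  if (is.null(run)) {
    return(c(appearance_offset_min = NA_real_, lifetime_min = NA_real_))
  }
  c(appearance_offset_min = (completion_frame - run["start"]) * frame_interval,
    lifetime_min = run["length"] * frame_interval)
}

#' Ratiometric biosensor readout of one cell
#'
#' Mean green over the cell's pixels divided by mean red, each background
#' corrected. The ratio cancels cell-to-cell expression differences and
#' reports the sensor's binding state.
#'
#' @param pixels (row, col) matrix of cell pixels.
#' @param green,red Channel matrices.
#' @param background_green,background_red Background levels, AU per pixel.
#' @return Dimensionless ratio; `NA` if the corrected red mean is not
#'   positive (cell skipped).
#' @export
biosensor_ratio <- function(pixels, green, red, background_green = 0,
                            background_red = 0) {
  g <- mean(green[pixels]) - background_green
  r <- mean(red[pixels]) - background_red
  if (is.na(r) || r <= 0) return(NA_real_)
  g / r
}

#' Green/red ratio series over a division event
#'
#' Pre-completion frames use the mother's pixels; from completion on, the
#' union of the two daughters. Backgrounds are estimated per frame and
#' channel as the median of non-cell pixels.
#'
#' @inheritParams midcell_cluster_series
#' @param red List of red-channel matrices.
#' @return Numeric per-frame ratio vector.
#' @export
biosensor_series <- function(event, masks, green, red) {
  vapply(seq_along(masks), function(t) {
    mask <- masks[[t]]
    px <- if (t < event$completion_frame) {
      which(mask == event$mother_label, arr.ind = TRUE)
    } else {
      which(mask == event$daughter1 | mask == event$daughter2, arr.ind = TRUE)
    }
    if (nrow(px) == 0L) return(NA_real_)
    biosensor_ratio(px, green[[t]], red[[t]],
                    estimate_background(green[[t]], mask),
                    estimate_background(red[[t]], mask))
  }, numeric(1))
}

#' Burst onset and duration from a ratio series
#'
#' A frame is "high" when its ratio exceeds `baseline median + k_burst *`
#' `baseline MAD`, the baseline being the earliest `baseline_frames` frames
#' of the mother. The burst is the longest contiguous high run (ties go to
#' the earliest); onset is `(completion frame - first high frame) *`
#' `frame_interval` and duration the run length times the frame interval.
#'
#' @param ratio Per-frame ratio vector (see [biosensor_series()]).
#' @param completion_frame Index of t = 0.
#' @param frame_interval Minutes per frame.
#' @param baseline_frames Number of initial frames defining the baseline
#'   (default 5; the MAD of very short baselines degenerates towards zero,
#'   which would put the threshold inside the noise band).
#' @param k_burst MAD multiplier (default 5; ratio bursts are near-binary).
#' @return Named numeric: `onset_offset_min`, `duration_min`; both `NA` for
#'   a flat trace.
#' @export
burst_timing <- function(ratio, completion_frame, frame_interval,
                         baseline_frames = 5L, k_burst = 5) {
  if (length(ratio) <= baseline_frames) stop("ratio series too short")
  base <- ratio[seq_len(baseline_frames)]
  # noise scale: the baseline MAD, floored by the burst-insensitive MAD of
  # successive differences (a handful of baseline frames can have a
  # degenerately small MAD by chance)
  scale <- max(mad_raw(base, na.rm = TRUE),
               mad_raw(diff(ratio[!is.na(ratio)])) / sqrt(2))
  thr <- stats::median(base, na.rm = TRUE) + k_burst * scale
  run <- principal_run(!is.na(ratio) & ratio > thr)
  if (is.null(run)) {
    return(c(onset_offset_min = NA_real_, duration_min = NA_real_))
  }
  c(onset_offset_min = (completion_frame - run["start"]) * frame_interval,
    duration_min = run["length"] * frame_interval)
}

#' Daughter-pair polarity symmetry across a division
#'
#' Quantifies polar fluorescence in the predivisional mother `offset_min`
#' minutes before completion and in both daughters `offset_min` minutes
#' after, returning the asymmetry index of each. Daughters are sorted
#' ascending by omega (most symmetric first).
#'
#' @inheritParams midcell_cluster_series
#' @param offset_min Minutes before/after completion at which to measure.
#' @param frame_interval Minutes per frame.
#' @param k_sd,min_pixels,cap_depth_um,pixel_size_um Polarity quantification
#'   settings (see [polarity_record()]).
#' @return A list: `mother` (one-row polarity record) and `daughters`
#'   (two-row polarity record data.frame, sorted by omega). Errors if a
#'   daughter is missing from the measurement frame.
#' @export
daughter_symmetry <- function(event, masks, green, offset_min, frame_interval,
                              k_sd = 2, min_pixels = 3L, cap_depth_um = 0.35,
                              pixel_size_um = 0.1) {
  steps <- round(offset_min / frame_interval)
  t_pre <- event$completion_frame - steps
  t_post <- event$completion_frame + steps
  if (t_pre < 1 || t_post > length(masks)) {
    stop("offset_min outside the recorded window")
  }
  rec_at <- function(t, label) {
    mask <- masks[[t]]
    if (!any(mask == label)) stop("label ", label, " lost from frame ", t)
    bg <- estimate_background(green[[t]], mask)
    cells <- cell_regions(mask, frame = t)
    cell <- cells[[which(vapply(cells, `[[`, numeric(1), "label") == label)]]
    cell <- find_poles(cell, cap_depth_um, pixel_size_um)
    polarity_record(cell, green[[t]], k_sd = k_sd, min_pixels = min_pixels,
                    background = bg)
  }
  mother <- rec_at(t_pre, event$mother_label)
  d <- rbind(rec_at(t_post, event$daughter1), rec_at(t_post, event$daughter2))
  d <- d[order(d$omega), ]
  list(mother = mother, daughters = d)
}

#' Run the full time-lapse pipeline on one division movie
#'
#' Links the lineage, locates the division event, and extracts mid-cell
#' cluster timing and/or biosensor burst timing.
#'
#' @param movie Output of [make_division_movie()] (or a list with `frames`
#'   of `green`/`red`/`mask` and `params` holding `frame_interval_min`).
#' @param what Any of `"cluster"`, `"burst"`.
#' @param k_sd,min_pixels,cap_depth_um,pixel_size_um,baseline_frames,k_burst
#'   Stage settings.
#' @param iou_min Lineage-linking threshold.
#' @return One-row data.frame with `completion_frame`, and per requested
#'   stage `appearance_offset_min`/`lifetime_min` and
#'   `onset_offset_min`/`duration_min`; zero rows if no event was found.
#' @export
analyze_division_movie <- function(movie, what = c("cluster", "burst"),
                                   k_sd = 2, min_pixels = 3L,
                                   cap_depth_um = 0.35, pixel_size_um = 0.1,
                                   baseline_frames = 3L, k_burst = 5,
                                   iou_min = 0.2) {
  what <- match.arg(what, several.ok = TRUE)
  masks <- lapply(movie$frames, `[[`, "mask")
  green <- lapply(movie$frames, `[[`, "green")
  dt <- movie$params$frame_interval_min
  lin <- link_lineage(masks, iou_min = iou_min)
  if (nrow(lin$events) == 0L) {
    return(data.frame(completion_frame = integer(0)))
  }
  event <- lin$events[1, ]
  out <- data.frame(completion_frame = event$completion_frame)
  if ("cluster" %in% what) {
    pres <- midcell_cluster_series(event, masks, green, k_sd = k_sd,
                                   min_pixels = min_pixels,
                                   cap_depth_um = cap_depth_um,
                                   pixel_size_um = pixel_size_um)
    out <- cbind(out, t(cluster_timing(pres, event$completion_frame, dt)))
  }
  if ("burst" %in% what) {
    red <- lapply(movie$frames, `[[`, "red")
    ratio <- biosensor_series(event, masks, green, red)
    out <- cbind(out, t(burst_timing(ratio, event$completion_frame, dt,
                                     baseline_frames = baseline_frames,
                                     k_burst = k_burst)))
  }
  out
}
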