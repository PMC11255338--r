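#' Write a list of matrices as a multi-page 16-bit TIFF
#'
#' Values are rounded to integers and must lie in `[0, 65535]`. Used for both
#' intensity images (AU are stored as integer counts) and label masks.
#'
#' @param pages A matrix or list of matrices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  pages <- lapply(pages, function(m) {
    m <- round(m)
    if (any(m < 0) || any(m > 65535)) {
      stop("values outside [0, 65535] cannot be stored as 16-bit TIFF")
    }
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as a list of integer-valued matrices
#'
#' @param path TIFF file path.
#' @return List of matrices with native integer values.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]
    storage.mode(m) <- "double"
    m
  })
}

#' Build cell regions from a label mask
#'
#' One region per non-zero label. Labels are preserved verbatim; no
#' relabelling is performed. Coordinates are 1-based (row, col).
#'
#' @param mask Integer-valued label matrix (0 = background).
#' @param frame Frame index stored in each region.
#' @param min_area_px Regions smaller than this are dropped.
#' @return A list of `cell_region` objects (fields: `frame`, `label`,
#'   `pixels`, `area_px`; pole fields are filled by [find_poles()]).
#' @export
cell_regions <- function(mask, frame = 1L, min_area_px = 5L) {
  if (any(mask != round(mask))) stop("mask must be integer-valued")
  labs <- sort(unique(mask[mask > 0]))
  out <- list()
  for (lab in labs) {
    idx <- which(mask == lab)
    if (length(idx) < min_area_px) next
    px <- as_pixel_matrix(cbind(((idx - 1L) %% nrow(mask)) + 1L,
                                ((idx - 1L) %/% nrow(mask)) + 1L))
    out[[length(out) + 1L]] <- structure(
      list(frame = frame, label = lab, pixels = px, area_px = nrow(px),
           pole_tips = NULL, pole_caps = NULL, cytoplasm = NULL),
      class = "cell_region"
    )
  }
  out
}

#' @export
print.cell_region <- function(x, ...) {
  cat(sprintf("<cell_region> frame %d label %d: %d px%s\n", x$frame, x$label,
              x$area_px, if (is.null(x$pole_tips)) "" else ", poles assigned"))
  invisible(x)
}

#' Load multi-channel images and label masks from TIFF files
#'
#' `image_path` may name one file per channel (named vector); each file holds
#' one page per frame. The mask file holds one integer label page per frame.
#'
#' @param image_path Named character vector of channel TIFF paths.
#' @param mask_path Path to the label-mask TIFF.
#' @param min_area_px Passed to [cell_regions()].
#' @return A list with one element per frame, each a list with `channels`
#'   (named list of matrices), `mask`, and `regions`.
#' @export
load_labeled_frames <- function(image_path, mask_path, min_area_px = 5L) {
  if (is.null(names(image_path))) {
    names(image_path) <- if (length(image_path) == 1L) "ch1" else
      paste0("ch", seq_along(image_path))
  }
  masks <- read_image_stack(mask_path)
  chans <- lapply(image_path, read_image_stack)
  n_frames <- length(masks)
  for (ch in names(chans)) {
    if (length(chans[[ch]]) != n_frames) {
      stop("channel '", ch, "' has a different number of frames than the mask")
    }
    if (!all(vapply(chans[[ch]], function(m) identical(dim(m), dim(masks[[1]])),
                    logical(1)))) {
      stop("image and mask shapes do not match")
    }
  }
  lapply(seq_len(n_frames), function(t) {
    list(
      channels = lapply(chans, `[[`, t),
      mask = masks[[t]],
      regions = cell_regions(masks[[t]], frame = t, min_area_px = min_area_px)
    )
  })
}

# Geodesic distances within the pixel set, approximated by a 16-neighbourhood
# chamfer metric (axis, diagonal and knight moves with Euclidean weights);
# the knight moves keep the metric near-isotropic (~2% worst-case error), so
# pole caps barely change when a cell is rotated.
geodesic_distances <- function(px, from) {
  n <- nrow(px)
  key <- paste(px[, 1], px[, 2])
  idx <- stats::setNames(seq_len(n), key)
  off <- cbind(c(0, 1, 1, 1, 1, 2, 2, 1),
               c(1, 0, 1, -1, 2, 1, -1, -2))
  w8 <- c(1, 1, sqrt(2), sqrt(2), sqrt(5), sqrt(5), sqrt(5), sqrt(5))
  ei <- integer(0); ew <- numeric(0)
  for (k in seq_len(nrow(off))) {
    nb <- paste(px[, 1] + off[k, 1], px[, 2] + off[k, 2])
    hit <- idx[nb]
    ok <- !is.na(hit)
    if (any(ok)) {
      ei <- c(ei, rbind(which(ok), unname(hit[ok])))
      ew <- c(ew, rep(w8[k], sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(ei)) g <- igraph::add_edges(g, ei, weight = ew)
  igraph::distances(g, v = from)
}

# Double-sweep tip finding: farthest pixel from an arbitrary start, then the
# farthest pixel from that; returns row indices into px plus the geodesic
# distance maps from each tip.
find_tips <- function(px) {
  d0 <- geodesic_distances(px, 1L)[1, ]
  d0[!is.finite(d0)] <- -Inf
  p1 <- which.max(d0)
  d1 <- geodesic_distances(px, p1)[1, ]
  d1[!is.finite(d1)] <- -Inf
  p2 <- which.max(d1)
  d2 <- geodesic_distances(px, p2)[1, ]
  list(tips = c(p1, p2), d1 = d1, d2 = d2)
}

#' Locate cell poles and pole caps
#'
#' Pole tips are the endpoints of the longest geodesic path through the pixel
#' set (found by the standard double-sweep: the farthest pixel from an
#' arbitrary start, then the farthest pixel from that). Pole caps are the
#' pixels within `cap_depth_um` of each tip measured geodesically; each pixel
#' is assigned to its nearer tip so the caps are always disjoint, and the
#' cytoplasm is everything else. No axis alignment is assumed.
#'
#' @param cell A `cell_region` from [cell_regions()].
#' @param cap_depth_um Cap depth in micrometres. The default, half a typical
#'   cell width, makes the cap scale with the organism.
#' @param pixel_size_um Micrometres per pixel.
#' @return The `cell_region` with `pole_tips` (2 x 2 matrix of (row, col)),
#'   `pole_caps` (list of two integer index vectors into `pixels`) and
#'   `cytoplasm` (index vector) filled in.
#' @export
find_poles <- function(cell, cap_depth_um = 0.35, pixel_size_um = 0.1) {
  stopifnot(inherits(cell, "cell_region"))
  px <- cell$pixels
  if (nrow(px) < 2L) stop("degenerate region: need at least 2 pixels")
  ft <- find_tips(px)
  p1 <- ft$tips[1]; p2 <- ft$tips[2]
  d1 <- ft$d1; d2 <- ft$d2

  cap_px <- cap_depth_um / pixel_size_um
  nearer1 <- d1 <= d2
  cap1 <- which(d1 <= cap_px & nearer1)
  cap2 <- which(d2 <= cap_px & !nearer1)
  cyto <- setdiff(seq_len(nrow(px)), c(cap1, cap2))

  cell$pole_tips <- px[c(p1, p2), , drop = FALSE]
  cell$pole_caps <- list(cap1, cap2)
  cell$cytoplasm <- cyto
  cell
}

#' Estimate the flat background level of an image
#'
#' Median intensity of non-cell pixels. The mask is dilated first so that
#' halo pixels at cell boundaries do not bias the estimate; the median makes
#' the estimate robust to hot pixels.
#'
#' @param image Intensity matrix.
#' @param mask Label matrix of the same shape.
#' @param dilate_px Mask dilation radius in pixels (default 2).
#' @return Background level, AU per pixel.
#' @export
estimate_background <- function(image, mask, dilate_px = 2L) {
  stopifnot(identical(dim(image), dim(mask)))
  bg <- !dilate_mask(mask > 0, dilate_px)
  if (!any(bg)) stop("mask (after dilation) covers the whole image")
  stats::median(image[bg])
}

#' Background-corrected, area-normalized cell fluorescence
#'
#' `(sum of intensity over the cell - background * area) / area`, i.e. the
#' mean per-pixel signal above background. Because of the area normalization
#' the value is independent of cell size for uniformly fluorescent cells and
#' serves as a concentration proxy.
#'
#' @param cell A `cell_region`.
#' @param image Intensity matrix.
#' @param background Background level, AU per pixel (see
#'   [estimate_background()]).
#' @return AU per pixel.
#' @export
normalized_cell_fluorescence <- function(cell, image, background = 0) {
  v <- image[cell$pixels]
  (sum(v) - background * cell$area_px) / cell$area_px
}

# Intensity values of a subset (index vector into cell$pixels).
pixel_values <- function(cell, image, idx = NULL) {
  px <- if (is.null(idx)) cell$pixels else cell$pixels[idx, , drop = FALSE]
  image[px]
}
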