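#' Parameters for a synthetic snapshot scene
#'
#' Bundles and validates the parameters controlling [make_snapshot_scene()].
#' Cells are rendered as spherocylinders (rods with hemispherical caps) at
#' random orientations on a flat background. Each cell carries a stated
#' fraction of its total fluorescence in a compact cluster at each pole; the
#' remainder is spread uniformly over the cytoplasm.
#'
#' @param n_cells Number of cells to place.
#' @param cell_length_um `c(mean, sd)` tip-to-tip cell length, micrometres.
#' @param cell_width_um `c(mean, sd)` cell width, micrometres.
#' @param pixel_size_um Physical pixel size, micrometres per pixel.
#' @param cytoplasm_intensity Mean cytoplasmic signal, AU per pixel (above
#'   background).
#' @param background_intensity Flat background level, AU per pixel.
#' @param polar_fractions Length-2 vector: fraction of each cell's total
#'   signal placed in a cluster at pole 1 and pole 2. Each in `[0, 1]`,
#'   summing to at most 1.
#' @param cluster_radius_px Radius (pixels) of the polar cluster disc.
#' @param noise_gaussian_sd SD of additive Gaussian read noise, AU.
#' @param poisson_scaling Photons per AU for the Poisson (shot-noise) stage;
#'   use `Inf` to disable shot noise.
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @param randomize_orientation Draw a random axis angle per cell (default);
#'   if `FALSE` all cells are horizontal.
#' @return A list of class `"scene_params"`.
#' @export
scene_params <- function(n_cells = 50,
                         cell_length_um = c(6, 1),
                         cell_width_um = c(0.7, 0.05),
                         pixel_size_um = 0.1,
                         cytoplasm_intensity = 150,
                         background_intensity = 100,
                         polar_fractions = c(0.15, 0.05),
                         cluster_radius_px = 1.5,
                         noise_gaussian_sd = 5,
                         poisson_scaling = 1,
                         seed = 1L,
                         randomize_orientation = TRUE) {
  check_mean_sd(cell_length_um, "cell_length_um")
  check_mean_sd(cell_width_um, "cell_width_um")
  stopif_neg(pixel_size_um, "pixel_size_um")
  stopif_neg(cytoplasm_intensity, "cytoplasm_intensity")
  stopif_neg(background_intensity, "background_intensity")
  stopif_neg(noise_gaussian_sd, "noise_gaussian_sd")
  if (length(polar_fractions) != 2L || any(polar_fractions < 0) ||
      any(polar_fractions > 1) || sum(polar_fractions) > 1) {
    stop("'polar_fractions' must be two fractions in [0,1] summing to <= 1")
  }
  if (!(is.infinite(poisson_scaling) || poisson_scaling > 0)) {
    stop("'poisson_scaling' must be > 0 or Inf")
  }
  if (n_cells < 1) stop("'n_cells' must be >= 1")
  structure(
    list(
      n_cells = as.integer(n_cells),
      cell_length_um = cell_length_um, cell_width_um = cell_width_um,
      pixel_size_um = pixel_size_um,
      cytoplasm_intensity = cytoplasm_intensity,
      background_intensity = background_intensity,
      polar_fractions = polar_fractions,
      cluster_radius_px = cluster_radius_px,
      noise_gaussian_sd = noise_gaussian_sd,
      poisson_scaling = poisson_scaling,
      seed = seed,
      randomize_orientation = isTRUE(randomize_orientation)
    ),
    class = "scene_params"
  )
}

# Pixel set of a spherocylinder: pixels whose centre lies within width/2 of
# the centreline segment between the two cap centres. Returns an integer
# (row, col) matrix; pixels outside the image are dropped by the caller.
spherocylinder_pixels <- function(center, angle, length_px, width_px) {
  half <- max((length_px - width_px) / 2, 0)
  u <- c(cos(angle), sin(angle))
  a <- center - half * u
  b <- center + half * u
  rad <- width_px / 2
  r0 <- floor(min(a[1], b[1]) - rad - 1)
  r1 <- ceiling(max(a[1], b[1]) + rad + 1)
  c0 <- floor(min(a[2], b[2]) - rad - 1)
  c1 <- ceiling(max(a[2], b[2]) + rad + 1)
  grid <- expand.grid(row = r0:r1, col = c0:c1)
  p <- cbind(grid$row, grid$col)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    d2 <- (p[, 1] - a[1])^2 + (p[, 2] - a[2])^2
  } else {
    t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (p[, 1] - (a[1] + t * ab[1]))^2 + (p[, 2] - (a[2] + t * ab[2]))^2
  }
  keep <- d2 <= rad^2
  list(
    pixels = as_pixel_matrix(p[keep, , drop = FALSE]),
    cap_centers = rbind(a, b),
    tips = rbind(a - rad * u, b + rad * u)
  )
}

# Apply the two-stage camera noise model: Poisson on
# (signal + background) * poisson_scaling, rescaled, then Gaussian read noise.
apply_camera_noise <- function(img, poisson_scaling, gaussian_sd) {
  if (is.finite(poisson_scaling)) {
    img[] <- stats::rpois(length(img), pmax(img, 0) * poisson_scaling) /
      poisson_scaling
  }
  if (gaussian_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, gaussian_sd)
  }
  img
}

#' Render a synthetic snapshot scene with ground truth
#'
#' Places `n_cells` non-overlapping spherocylindrical cells on a flat
#' background, deposits the configured fraction of each cell's total signal
#' in a disc at each pole, applies Poisson-then-Gaussian camera noise, and
#' returns the image, the label mask, and a per-cell ground-truth table.
#'
#' The truth asymmetry index is computed from the placed (noiseless) polar
#' fractions: `omega = (f1 - f2) / (f1 + f2)` with `f1 >= f2`, `NA` when both
#' fractions are zero (diffuse cell).
#'
#' @param params A [scene_params()] object.
#' @param max_tries Placement retries per cell before giving up.
#' @return A list with elements `image` (matrix, AU), `mask` (integer label
#'   matrix, 0 = background), `truth` (data.frame: `label`, `f1_true`,
#'   `f2_true`, `omega_true`, `pattern_true`, `area_px`) and `params`.
#' @export
make_snapshot_scene <- function(params = scene_params(), max_tries = 200L) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, {
    px_per_um <- 1 / params$pixel_size_um
    mean_len <- params$cell_length_um[1] * px_per_um
    mean_wid <- params$cell_width_um[1] * px_per_um
    mean_area <- mean_len * mean_wid
    side <- ceiling(sqrt(params$n_cells * mean_area / 0.12)) + ceiling(mean_len)
    mask <- matrix(0L, side, side)
    occupied <- matrix(FALSE, side, side)
    signal <- matrix(0, side, side)

    f <- params$polar_fractions
    truth <- vector("list", params$n_cells)

    for (i in seq_len(params$n_cells)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        len <- max(stats::rnorm(1, mean_len, params$cell_length_um[2] * px_per_um),
                   2 * mean_wid)
        wid <- max(stats::rnorm(1, mean_wid, params$cell_width_um[2] * px_per_um), 3)
        ang <- if (params$randomize_orientation) stats::runif(1, 0, pi) else 0
        margin <- len / 2 + 2
        ctr <- stats::runif(2, margin, side - margin)
        sc <- spherocylinder_pixels(ctr, ang, len, wid)
        px <- sc$pixels
        if (nrow(px) == 0 || any(px < 1) || any(px > side)) next
        lin <- px[, 1] + (px[, 2] - 1L) * side
        # 1-pixel clearance between neighbouring cells
        clear <- matrix(FALSE, side, side); clear[lin] <- TRUE
        clear <- dilate_mask(clear, 1L)
        if (any(occupied & clear)) next

        occupied <- occupied | clear
        mask[lin] <- i

        area <- nrow(px)
        total <- params$cytoplasm_intensity * area / max(1 - sum(f), 1e-9)
        signal[lin] <- signal[lin] + params$cytoplasm_intensity
        # order pixels as a mask extraction would (column-major) so the tip
        # pixels the downstream pole-finder reports anchor the clusters
        ord <- order(px[, 2], px[, 1])
        px <- px[ord, , drop = FALSE]
        lin <- lin[ord]
        tips <- find_tips(px)$tips
        for (p in 1:2) {
          if (f[p] <= 0) next
          cc <- px[tips[p], ]
          d2 <- (px[, 1] - cc[1])^2 + (px[, 2] - cc[2])^2
          disc <- which(d2 <= params$cluster_radius_px^2)
          signal[lin[disc]] <- signal[lin[disc]] + f[p] * total / length(disc)
        }
        f1 <- max(f); f2 <- min(f)
        omega <- if (f1 + f2 > 0) (f1 - f2) / (f1 + f2) else NA_real_
        truth[[i]] <- data.frame(
          label = i, f1_true = f1, f2_true = f2, omega_true = omega,
          pattern_true = if (is.na(omega)) "diffuse" else classify_pattern(omega),
          area_px = area
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf("could not place cell %d without overlap after %d tries",
                     i, max_tries))
      }
    }

    image <- apply_camera_noise(signal + params$background_intensity,
                                params$poisson_scaling,
                                params$noise_gaussian_sd)
    list(image = image, mask = mask,
         truth = do.call(rbind, truth), params = params)
  })
}
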