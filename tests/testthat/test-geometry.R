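test_that("TIFF round trip preserves integer images and masks", {
  img <- matrix(round(runif(200, 0, 4000)), 10, 20)
  mask <- matrix(sample(0:3, 200, replace = TRUE), 10, 20)
  f1 <- tempfile(fileext = ".tif"); f2 <- tempfile(fileext = ".tif")
  write_image_stack(list(img, img + 1), f1)
  write_image_stack(list(mask, mask), f2)
  back <- read_image_stack(f1)
  expect_length(back, 2)
  expect_equal(back[[1]], img, ignore_attr = TRUE)
  expect_equal(back[[2]], img + 1, ignore_attr = TRUE)
  frames <- load_labeled_frames(c(green = f1), f2, min_area_px = 1)
  expect_length(frames, 2)
  expect_length(frames[[1]]$regions, length(unique(mask[mask > 0])))
  # labels preserved verbatim
  labs <- vapply(frames[[1]]$regions, `[[`, numeric(1), "label")
  expect_setequal(labs, sort(unique(mask[mask > 0])))
})

test_that("load_labeled_frames rejects shape mismatches", {
  f1 <- tempfile(fileext = ".tif"); f2 <- tempfile(fileext = ".tif")
  write_image_stack(matrix(1, 5, 5), f1)
  write_image_stack(matrix(0L, 6, 6), f2)
  expect_error(load_labeled_frames(c(g = f1), f2), "shape")
})

test_that("cell_regions extracts one region per label and skips small ones", {
  mask <- matrix(0L, 10, 10)
  mask[2:5, 2:5] <- 1L
  mask[8:9, 8:9] <- 7L     # 4 px, below default minimum
  regs <- cell_regions(mask)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$label, 1)
  expect_equal(regs[[1]]$area_px, 16)
  regs2 <- cell_regions(mask, min_area_px = 1L)
  expect_length(regs2, 2)
  expect_error(cell_regions(matrix(0.5, 3, 3)), "integer")
  expect_length(cell_regions(matrix(0L, 4, 4)), 0)
})

test_that("find_poles on a rectangle matches the brute-force geodesic oracle", {
  cellm <- make_rect_cell(8, 40)
  cell <- cell_regions(cellm$mask)[[1]]
  cell <- find_poles(cell, cap_depth_um = 0.8, pixel_size_um = 0.1)  # 8 px
  # tips lie in the extreme columns of the rectangle
  cols <- range(cell$pixels[, 2])
  expect_setequal(cell$pole_tips[, 2], cols)
  # oracle: independent relaxation-based geodesic distances from the tips
  px <- cell$pixels
  tip_idx <- vapply(1:2, function(k) {
    which(px[, 1] == cell$pole_tips[k, 1] & px[, 2] == cell$pole_tips[k, 2])
  }, integer(1))
  d1 <- oracle_geodesic(px, tip_idx[1])
  d2 <- oracle_geodesic(px, tip_idx[2])
  cap1 <- which(d1 <= 8 & d1 <= d2)
  cap2 <- which(d2 <= 8 & d2 < d1)
  expect_setequal(cell$pole_caps[[1]], cap1)
  expect_setequal(cell$pole_caps[[2]], cap2)
  # symmetric construction: equal cap sizes
  expect_equal(length(cell$pole_caps[[1]]), length(cell$pole_caps[[2]]))
})

test_that("pole caps and cytoplasm exactly partition the cell", {
  sc <- scene_noiseless(n_cells = 6, seed = 9)
  for (cell in cell_regions(sc$mask)) {
    cell <- find_poles(cell, 0.35, 0.1)
    idx <- c(cell$pole_caps[[1]], cell$pole_caps[[2]], cell$cytoplasm)
    expect_equal(sort(idx), seq_len(cell$area_px))
    expect_length(intersect(cell$pole_caps[[1]], cell$pole_caps[[2]]), 0)
  }
})

test_that("find_poles is rotation-tolerant and accepts antipodal disc tips", {
  # cap areas of a rod rendered at different orientations agree within 5%
  # (tested at a resolution where discretization noise is below that)
  caps <- vapply(c(0, 20, 35, 50, 70, 90), function(deg) {
    sp <- polburst:::spherocylinder_pixels(c(100, 100), deg * pi / 180,
                                           120, 20)
    mask <- matrix(0L, 200, 200)
    mask[sp$pixels] <- 1L
    cell <- find_poles(cell_regions(mask)[[1]], 1.0, 0.1)
    mean(lengths(cell$pole_caps))
  }, numeric(1))
  expect_lt(diff(range(caps)) / mean(caps), 0.05)
  # disc: tips roughly antipodal, caps symmetric within discretization
  mask3 <- matrix(0L, 40, 40)
  for (r in 1:40) for (c in 1:40) {
    if ((r - 20)^2 + (c - 20)^2 <= 100) mask3[r, c] <- 1L
  }
  disc <- find_poles(cell_regions(mask3)[[1]], 0.3, 0.1)
  tipd <- sqrt(sum((disc$pole_tips[1, ] - disc$pole_tips[2, ])^2))
  expect_gt(tipd, 2 * 10 * 0.85)
  expect_lt(abs(diff(lengths(disc$pole_caps))) / mean(lengths(disc$pole_caps)),
            0.3)
  # degenerate region
  m <- matrix(0L, 3, 3); m[2, 2] <- 1L
  expect_error(find_poles(cell_regions(m, min_area_px = 1)[[1]]), "degenerate")
})

test_that("find_poles does not depend on label value or image position", {
  base <- make_rect_cell(6, 24)
  c1 <- find_poles(cell_regions(base$mask)[[1]], 0.35, 0.1)
  mask2 <- matrix(0L, 40, 60)
  mask2[20 + seq_len(6), 15 + seq_len(24)] <- 99L
  c2 <- find_poles(cell_regions(mask2)[[1]], 0.35, 0.1)
  expect_equal(lengths(c1$pole_caps), lengths(c2$pole_caps))
  expect_equal(length(c1$cytoplasm), length(c2$cytoplasm))
})

test_that("background estimation is a robust median of non-cell pixels", {
  cellm <- make_rect_cell(8, 20, base = 500)
  img <- cellm$image
  img[cellm$mask == 0] <- 70
  expect_equal(estimate_background(img, cellm$mask), 70)
  img[1, 1] <- 1e6  # hot pixel does not move the median
  expect_equal(estimate_background(img, cellm$mask), 70)
  expect_error(estimate_background(img, matrix(1L, nrow(img), ncol(img))),
               "whole image")
  # synthetic scene: recovered within noise
  sc <- make_snapshot_scene(scene_params(n_cells = 5, seed = 3))
  bg <- estimate_background(sc$image, sc$mask)
  expect_lt(abs(bg - sc$params$background_intensity), 3)
})

test_that("normalized cell fluorescence is background-corrected, linear and area-free", {
  mask <- matrix(0L, 12, 12)
  mask[3:8, 3:8] <- 1L
  cell <- cell_regions(mask)[[1]]
  img <- matrix(40, 12, 12)
  img[mask == 1L] <- 130
  expect_equal(normalized_cell_fluorescence(cell, img, background = 40), 90)
  expect_equal(normalized_cell_fluorescence(cell, matrix(40, 12, 12), 40), 0)
  img2 <- matrix(40, 12, 12); img2[mask == 1L] <- 40 + 2 * 90
  expect_equal(normalized_cell_fluorescence(cell, img2, 40), 180)
  # independent of area for uniform cells
  for (w in c(3, 6, 9)) {
    m <- matrix(0L, 15, 15); m[seq_len(w) + 2, seq_len(w) + 2] <- 1L
    cl <- cell_regions(m, min_area_px = 1)[[1]]
    im <- matrix(40, 15, 15); im[m == 1L] <- 130
    expect_equal(normalized_cell_fluorescence(cl, im, 40), 90)
  }
})
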