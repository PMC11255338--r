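test_that("snapshot scenes are seed-deterministic", {
  a <- make_snapshot_scene(scene_params(n_cells = 6, seed = 11))
  b <- make_snapshot_scene(scene_params(n_cells = 6, seed = 11))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$truth, b$truth)
  c <- make_snapshot_scene(scene_params(n_cells = 6, seed = 12))
  expect_false(identical(a$image, c$image))
})

test_that("scene parameter validation rejects impossible settings", {
  expect_error(scene_params(polar_fractions = c(0.7, 0.5)), "polar_fractions")
  expect_error(scene_params(polar_fractions = c(-0.1, 0.2)), "polar_fractions")
  expect_error(scene_params(cytoplasm_intensity = -5), "cytoplasm")
  expect_error(make_snapshot_scene(scene_params(n_cells = 500, seed = 1),
                                   max_tries = 2),
               "overlap")
})

test_that("cells are disjoint and truth omega matches placed fractions", {
  sc <- scene_noiseless(n_cells = 12, polar_fractions = c(0.3, 0.1), seed = 4)
  expect_equal(nrow(sc$truth), 12)
  # labels all present, no overlap by construction of a label mask
  expect_setequal(unique(sc$truth$label), 1:12)
  expect_equal(sc$truth$omega_true, rep((0.3 - 0.1) / 0.4, 12))
  expect_true(all(sc$truth$pattern_true == "asymmetric"))
})

test_that("symmetric and unipolar constructions give omega 0 and 1", {
  sym <- scene_noiseless(n_cells = 5, polar_fractions = c(0.2, 0.2), seed = 2)
  expect_true(all(sym$truth$omega_true == 0))
  uni <- scene_noiseless(n_cells = 5, polar_fractions = c(0.4, 0), seed = 2)
  expect_true(all(uni$truth$omega_true == 1))
  expect_true(all(uni$truth$pattern_true == "unipolar"))
  diff <- scene_noiseless(n_cells = 5, polar_fractions = c(0, 0), seed = 2)
  expect_true(all(is.na(diff$truth$omega_true)))
  expect_true(all(diff$truth$pattern_true == "diffuse"))
})

test_that("division movies are deterministic and respect the frame grid", {
  a <- make_division_movie(movie_params(seed = 3))
  b <- make_division_movie(movie_params(seed = 3))
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
  # truth offsets are multiples of the frame interval
  dt <- a$params$frame_interval_min
  expect_equal(a$truth$cluster_appearance_min %% dt, 0)
  # completion frame is the first frame with two labels
  nlabs <- vapply(a$frames, function(f) length(unique(f$mask[f$mask > 0])),
                  integer(1))
  expect_equal(which(nlabs == 2)[1], a$completion_frame)
})

test_that("a fixed 20-min appearance offset gives exactly 4 pre-completion frames", {
  mv <- make_division_movie(movie_params(
    cluster_appearance = c(20, 0), frame_interval_min = 5,
    noise_gaussian_sd = 0, poisson_scaling = Inf, seed = 1))
  masks <- lapply(mv$frames, `[[`, "mask")
  green <- lapply(mv$frames, `[[`, "green")
  ev <- link_lineage(masks)$events[1, ]
  pres <- midcell_cluster_series(ev, masks, green)
  expect_equal(sum(pres), 4)
  expect_true(all(which(pres) < ev$completion_frame))
})

test_that("burst amplitude 1 gives a flat ratio trace", {
  mv <- make_division_movie(movie_params(
    markers = "biosensor", burst_amplitude = 1, frame_interval_min = 10,
    noise_gaussian_sd = 0, poisson_scaling = Inf, seed = 2))
  masks <- lapply(mv$frames, `[[`, "mask")
  ev <- link_lineage(masks)$events[1, ]
  ratio <- biosensor_series(ev, masks, lapply(mv$frames, `[[`, "green"),
                            lapply(mv$frames, `[[`, "red"))
  expect_lt(diff(range(ratio)), 1e-9)
  bt <- burst_timing(ratio, ev$completion_frame, 10)
  expect_true(all(is.na(bt)))
})

test_that("track generator: zero-rate tracks never reverse, zero-SD speed is exact", {
  tk <- make_tracks(track_params(n_tracks = 10, reversal_rate_per_min = 0,
                                 heading_jitter_deg = 0,
                                 speed_um_min = c(3, 0), seed = 7))
  expect_true(all(tk$truth$n_reversals == 0))
  steps <- by(tk$tracks, tk$tracks$track_id, function(tr) {
    sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  })
  expect_true(all(abs(unlist(steps) - 3 * 0.5) < 1e-9))
})

test_that("mean truth reversal count converges to rate * duration", {
  tk <- make_tracks(track_params(n_tracks = 2000, reversal_rate_per_min = 0.2,
                                 duration_min = 15, seed = 8))
  lambdaT <- 0.2 * 15
  se <- sqrt(lambdaT / 2000)
  expect_lt(abs(mean(tk$truth$n_reversals) - lambdaT), 4 * se)
})

test_that("kinetics generator hits the model's anchor points without noise", {
  d <- make_kinetics_dataset("inhibition", list(V0 = 2, Ki = 15, h = 1.8),
                             x_values = c(0, 15, 30), replicates = 2,
                             noise_sd = 0, seed = 1)
  expect_equal(d$velocity[d$cdG == 0], c(2, 2))
  expect_equal(d$velocity[d$cdG == 15], c(1, 1))   # half-inhibition at Ki
  b <- make_kinetics_dataset("binding", list(Rmax = 3, KD = 3.5),
                             x_values = c(0, 3.5), replicates = 1,
                             noise_sd = 0, seed = 1)
  expect_equal(b$response, c(0, 1.5))               # half-saturation at KD
})

test_that("age sampler matches the closed-form tail fraction", {
  n <- 10000
  Td <- 300
  ages <- sample_population_ages(n, Td, seed = 123)
  expect_true(all(ages >= 0 & ages <= Td))
  for (delta in c(20, 60, 150)) {
    p_true <- 2^(delta / Td) - 1
    p_hat <- mean(ages >= Td - delta)
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(p_hat - p_true), 3 * se)
  }
  # degenerate windows
  expect_equal(mean(ages >= Td), 0)
  expect_equal(mean(ages >= 0), 1)
})
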