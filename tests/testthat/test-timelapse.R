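movie_stacks <- function(mv) {
  list(masks = lapply(mv$frames, `[[`, "mask"),
       green = lapply(mv$frames, `[[`, "green"),
       red = lapply(mv$frames, `[[`, "red"))
}

test_that("lineage linking finds the division at the first two-label frame", {
  mv <- make_division_movie(movie_params(seed = 3, noise_gaussian_sd = 0,
                                         poisson_scaling = Inf))
  st <- movie_stacks(mv)
  lin <- link_lineage(st$masks)
  expect_equal(nrow(lin$events), 1)
  expect_equal(lin$events$completion_frame, mv$completion_frame)
  expect_setequal(c(lin$events$daughter1, lin$events$daughter2), 2:3)
  # a movie truncated before the split has no events
  lin2 <- link_lineage(st$masks[seq_len(mv$completion_frame - 1L)])
  expect_equal(nrow(lin2$events), 0)
})

test_that("gradual constriction still dates completion at the label split", {
  mv <- make_division_movie(movie_params(seed = 4, gradual_constriction = TRUE))
  st <- movie_stacks(mv)
  lin <- link_lineage(st$masks)
  expect_equal(lin$events$completion_frame, mv$completion_frame)
})

test_that("cluster timing arithmetic matches the frame bookkeeping", {
  pres <- rep(FALSE, 25)
  pres[17:20] <- TRUE   # frames -4..-1 for completion at 21
  expect_equal(unname(cluster_timing(pres, 21, 5)), c(20, 20))
  pres2 <- rep(FALSE, 25); pres2[20] <- TRUE
  expect_equal(unname(cluster_timing(pres2, 21, 5)), c(5, 5))
  expect_true(all(is.na(cluster_timing(rep(FALSE, 25), 21, 5))))
  # isolated early false positive does not displace the principal run
  pres3 <- pres; pres3[3] <- TRUE
  expect_equal(unname(cluster_timing(pres3, 21, 5)), c(20, 20))
})

test_that("mid-cell presence follows the rendered window and threshold rule", {
  mv <- make_division_movie(movie_params(cluster_appearance = c(25, 0),
                                         noise_gaussian_sd = 0,
                                         poisson_scaling = Inf, seed = 6))
  st <- movie_stacks(mv)
  ev <- link_lineage(st$masks)$events[1, ]
  pres <- midcell_cluster_series(ev, st$masks, st$green)
  tm <- cluster_timing(pres, ev$completion_frame, 5)
  expect_equal(unname(tm), c(25, 25))
  # a movie without the marker yields an all-absent series
  mv0 <- make_division_movie(movie_params(markers = character(0),
                                          noise_gaussian_sd = 0,
                                          poisson_scaling = Inf, seed = 6))
  st0 <- movie_stacks(mv0)
  ev0 <- link_lineage(st0$masks)$events[1, ]
  expect_false(any(midcell_cluster_series(ev0, st0$masks, st0$green)))
})

test_that("biosensor ratio is the background-corrected green/red mean ratio", {
  px <- cbind(2:4, 2:4)
  g <- matrix(10, 6, 6); r <- matrix(5, 6, 6)
  expect_equal(biosensor_ratio(px, g, r), 2)
  expect_equal(biosensor_ratio(px, matrix(7, 6, 6), r,
                               background_green = 7), 0)
  expect_true(is.na(biosensor_ratio(px, g, r, background_red = 5)))
})

test_that("burst timing reads a step trace exactly and ignores flat traces", {
  ratio <- c(rep(1, 8), 3, 3, rep(1, 3))   # high at frames -2, -1
  expect_equal(unname(burst_timing(ratio, 11, 10)), c(20, 20))
  expect_true(all(is.na(burst_timing(rep(1, 13), 11, 10))))
})

test_that("timings are invariant to uniform intensity rescaling", {
  mv <- make_division_movie(movie_params(seed = 12,
                                         markers = c("midcell_cluster",
                                                     "biosensor"),
                                         frame_interval_min = 10))
  st <- movie_stacks(mv)
  ev <- link_lineage(st$masks)$events[1, ]
  pres1 <- midcell_cluster_series(ev, st$masks, st$green)
  ratio1 <- biosensor_series(ev, st$masks, st$green, st$red)
  sc_g <- lapply(st$green, function(m) 3.7 * m)
  sc_r <- lapply(st$red, function(m) 3.7 * m)
  expect_identical(midcell_cluster_series(ev, st$masks, sc_g), pres1)
  expect_equal(biosensor_series(ev, st$masks, sc_g, sc_r), ratio1)
  # quantization invariant: reported offsets are frame-interval multiples
  tm <- c(cluster_timing(pres1, ev$completion_frame, 10),
          burst_timing(ratio1, ev$completion_frame, 10))
  expect_true(all(tm[!is.na(tm)] %% 10 == 0))
})

test_that("noiseless movies recover every timing truth exactly", {
  for (s in 1:5) {
    mv <- make_division_movie(movie_params(
      seed = 30 + s, markers = "midcell_cluster", frame_interval_min = 5,
      noise_gaussian_sd = 0, poisson_scaling = Inf))
    res <- analyze_division_movie(mv, what = "cluster")
    expect_equal(res$appearance_offset_min, mv$truth$cluster_appearance_min)
    expect_equal(res$lifetime_min, mv$truth$cluster_lifetime_min)
    mvb <- make_division_movie(movie_params(
      seed = 60 + s, markers = "biosensor", frame_interval_min = 5,
      noise_gaussian_sd = 0, poisson_scaling = Inf))
    resb <- analyze_division_movie(mvb, what = "burst")
    expect_equal(resb$onset_offset_min, mvb$truth$burst_onset_min)
    expect_equal(resb$duration_min, mvb$truth$burst_duration_min)
  }
})

test_that("recovered timing distributions match the generating ones", {
  meas <- truth <- numeric(0)
  for (s in 1:40) {
    mv <- make_division_movie(movie_params(seed = 600 + s))
    r <- analyze_division_movie(mv, what = "cluster")
    meas <- c(meas, r$lifetime_min)
    truth <- c(truth, mv$truth$cluster_lifetime_min)
  }
  expect_gt(suppressWarnings(ks.test(meas[!is.na(meas)], truth)$p.value), 0.01)
})

test_that("daughter symmetry reflects the allocation of the released pool", {
  run_alloc <- function(alloc) {
    mv <- make_division_movie(movie_params(
      seed = 8, markers = "polar_protein", daughter_allocation = alloc,
      noise_gaussian_sd = 0, poisson_scaling = Inf))
    st <- movie_stacks(mv)
    ev <- link_lineage(st$masks)$events[1, ]
    daughter_symmetry(ev, st$masks, st$green, offset_min = 25,
                      frame_interval = 5)
  }
  even <- run_alloc(c(0.5, 0.5))
  expect_equal(even$mother$omega, 0)
  expect_equal(even$daughters$omega, c(0, 0))
  skew <- run_alloc(c(1, 0))
  expect_equal(skew$daughters$omega, c(1 / 3, 1), tolerance = 1e-12)
  expect_equal(skew$daughters$pattern, c("asymmetric", "unipolar"))
  # omega of the less-favoured daughter grows with allocation imbalance
  top <- vapply(list(c(0.5, 0.5), c(0.7, 0.3), c(0.9, 0.1), c(1, 0)),
                function(a) max(run_alloc(a)$daughters$omega), numeric(1))
  expect_true(all(diff(top) > 0))
})
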