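test_that("ladder calibration recovers exact power-law parameters", {
  d <- c(50, 100, 200)
  cal <- fit_ladder_calibration(data.frame(distance_px = d, kb = 100 * d^-0.8))
  expect_equal(cal$scale_A, 100, tolerance = 1e-12)
  expect_equal(cal$exponent_B, -0.8, tolerance = 1e-12)
  expect_lt(cal$fit_rmse, 1e-12)

  ## pure inverse law from hand-solvable bands
  cal2 <- fit_ladder_calibration(data.frame(distance_px = c(100, 200, 400),
                                            kb = c(10, 5, 2.5)))
  expect_equal(cal2$exponent_B, -1, tolerance = 1e-12)
  expect_equal(cal2$scale_A, 1000, tolerance = 1e-9)
  ## conversion reproduces the band sizes exactly
  expect_equal(calibration_kb(cal2, c(100, 200, 400)), c(10, 5, 2.5),
               tolerance = 1e-12)
})

test_that("ladder calibration rejects degenerate input", {
  expect_error(fit_ladder_calibration(data.frame(distance_px = c(1, 2),
                                                 kb = c(5, 3))), "at least 3")
  expect_error(fit_ladder_calibration(data.frame(distance_px = c(1, 2, 3),
                                                 kb = c(3, 4, 5))),
               "strictly decreasing")
  expect_error(fit_ladder_calibration(data.frame(distance_px = c(-1, 2, 3),
                                                 kb = c(5, 4, 3))), "positive")
})

test_that("nearest-ladder selection follows proximity with a leftmost tie-break", {
  gel <- gel_config()
  mk <- function(pos) fit_ladder_calibration(simulate_ladder(c(10, 5, 2.5), gel),
                                             position = pos,
                                             id = paste0("L", pos))
  ladders <- list(mk(1), mk(10), mk(20))
  expect_equal(select_nearest_ladder(4, ladders)$id, "L1")
  expect_equal(select_nearest_ladder(10, ladders)$id, "L10")   # co-located
  expect_equal(select_nearest_ladder(5.5, ladders)$id, "L1")   # equidistant
  expect_equal(select_nearest_ladder(15, ladders)$id, "L10")   # equidistant
  expect_error(select_nearest_ladder(3, list()), "no ladders")
})

test_that("background subtraction handles constants, spikes and the identity", {
  pos <- seq_len(200)
  flat <- lane_profile(pos, rep(0.3, 200))
  expect_equal(subtract_background(flat, "rolling_min")$od, rep(0, 200))

  spiked <- rep(0.2, 200)
  spiked[100] <- 1.2
  sp <- lane_profile(pos, spiked)
  out <- subtract_background(sp, "rolling_min")
  expect_equal(out$od[100], 1.0, tolerance = 1e-12)
  expect_equal(out$od[-100], rep(0, 199))
  out2 <- subtract_background(sp, "lane_flanks")
  expect_equal(out2$od[100], 1.0, tolerance = 1e-12)

  expect_identical(subtract_background(sp, "none")$od, sp$od)
  expect_error(subtract_background(sp, "spline"))
})

test_that("mean TRF reproduces the weighted-mean formula on hand-checkable profiles", {
  gel <- clean_gel()
  cal <- exact_calibration(gel)

  ## all OD at a single position of known molecular weight
  p1 <- spike_profile(7.3, 1, gel)
  expect_equal(mean_trf(p1, cal, c(3, 20))$mean_trf, 7.3, tolerance = 1e-9)

  ## OD (1, 1) at 4 and 8 kb: 2 / (1/4 + 1/8) = 5.333...
  p2 <- spike_profile(c(4, 8), c(1, 1), gel)
  r2 <- mean_trf(p2, cal, c(3, 20))
  expect_equal(r2$mean_trf, 16 / 3, tolerance = 1e-9)

  ## scale invariance: OD * 17 changes nothing
  p3 <- spike_profile(c(4, 8), c(17, 17), gel)
  expect_equal(mean_trf(p3, cal, c(3, 20))$mean_trf, r2$mean_trf,
               tolerance = 1e-12)
})

test_that("mean TRF windowing is a closed interval and errors on empty windows", {
  gel <- clean_gel()
  cal <- exact_calibration(gel)
  p <- spike_profile(c(3, 8, 20, 22), c(1, 1, 1, 1), gel)
  r <- mean_trf(p, cal, c(3, 20))
  ## edges at 3 and 20 included, 22 excluded
  expect_equal(r$mean_trf, 3 / (1 / 3 + 1 / 8 + 1 / 20), tolerance = 1e-9)
  expect_equal(r$fraction_od_in_window, 3 / 4, tolerance = 1e-9)
  expect_error(mean_trf(p, cal, c(9, 10)), "no OD mass")
  expect_error(mean_trf(p, cal, c(20, 3)), "low < high")
})

test_that("mean TRF is stable under profile resampling density", {
  cal <- exact_calibration(gel_config())
  trf <- trf_mixture(7, 1.2)
  est <- vapply(c(1000L, 2000L), function(np) {
    gel <- clean_gel(n_pixels = np)
    mean_trf(simulate_lane_profile(trf, gel), cal, c(3, 20))$mean_trf
  }, numeric(1))
  expect_lt(abs(est[2] - est[1]) / est[1], 0.005)
})

test_that("mean TRF increases when the TRF distribution shifts up in kb", {
  gel <- gel_config()
  cal <- exact_calibration(gel)
  means <- seq(5, 12, by = 1)
  est <- vapply(means, function(m) {
    p <- simulate_lane_profile(trf_mixture(m, 1), gel, seed = 100 + m)
    mean_trf(subtract_background(p, "lane_flanks"), cal, c(3, 20))$mean_trf
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("duplicate averaging is the arithmetic mean with a disagreement flag", {
  r <- average_duplicates(toy_trf_result(6.70), toy_trf_result(6.72, replicate = 2))
  expect_equal(r$mean_trf, 6.71)
  expect_length(r$qc_flags, 0)

  same <- average_duplicates(toy_trf_result(6.5), toy_trf_result(6.5, replicate = 2))
  expect_equal(same$mean_trf, 6.5)
  expect_length(same$qc_flags, 0)

  far <- average_duplicates(toy_trf_result(6.0), toy_trf_result(7.5, replicate = 2),
                            max_disagreement = 0.5)
  expect_equal(far$mean_trf, 6.75)
  expect_match(far$qc_flags, "duplicate_disagreement", all = FALSE)

  expect_error(average_duplicates(toy_trf_result(6, tissue = "L"),
                                  toy_trf_result(6, tissue = "M")),
               "share sample id and tissue")
})
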