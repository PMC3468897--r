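test_that("parameter validation rejects out-of-range values", {
  expect_error(larva_params(activity_fraction = 1.5), "activity_fraction")
  expect_error(larva_params(startle_response_prob = -0.1), "response_prob")
  expect_error(larva_params(circadian_peak_zt = 24), "circadian_peak_zt")
  expect_error(larva_params(habituation_decrement = 0), "habituation")
  expect_error(larva_params(pigment_gray_mean = 300), "8-bit")
})

test_that("simulate_trajectory rejects invalid durations and rates", {
  p <- larva_params()
  expect_error(simulate_trajectory(p, duration_s = 0), "duration")
  expect_error(simulate_trajectory(p, duration_s = 10, frame_rate_hz = -1),
               "frame_rate")
})

test_that("a larva with zero activity never moves", {
  tr <- simulate_trajectory(larva_params(activity_fraction = 0),
                            duration_s = 3600, seed = 5)
  expect_equal(length(unique(tr$x_mm)), 1)
  expect_equal(length(unique(tr$y_mm)), 1)
  expect_false(any(tr$moving))
  expect_equal(activity_profile(tr)$overall_pct, 0)
})

test_that("trajectories are seed-deterministic and confined to the well", {
  p <- larva_params(activity_fraction = 0.5, circadian_amplitude = 0.3)
  a <- simulate_trajectory(p, duration_s = 7200, seed = 11)
  b <- simulate_trajectory(p, duration_s = 7200, seed = 11)
  expect_identical(a, b)
  c_ <- simulate_trajectory(p, duration_s = 7200, seed = 12)
  expect_false(identical(a$x_mm, c_$x_mm))
  for (s in 1:5) {
    tr <- simulate_trajectory(p, duration_s = 3600, well_radius_mm = 3.5,
                              seed = s)
    expect_true(all(tr$x_mm^2 + tr$y_mm^2 <= 3.5^2 + 1e-9))
  }
})

test_that("measured time in motion matches the activity-fraction target", {
  # wildtype calibration, no rhythm, n = 48 larvae
  p <- larva_params(activity_fraction = 0.095, circadian_amplitude = 0)
  pct <- vapply(1:48, function(s) {
    tr <- simulate_trajectory(p, duration_s = 6 * 3600, seed = 100 + s)
    activity_profile(tr)$overall_pct
  }, numeric(1))
  expect_lt(abs(mean(pct) - 9.5), 1.5)
})

test_that("hourly activity peaks in the configured circadian bin", {
  p <- larva_params(activity_fraction = 0.2, circadian_amplitude = 0.5,
                    circadian_peak_zt = 13)
  hourly <- matrix(0, nrow = 20, ncol = 24)
  for (s in 1:20) {
    tr <- simulate_trajectory(p, duration_s = 24 * 3600, zt_start_h = 20,
                              seed = 200 + s)
    prof <- activity_profile(tr)
    h <- prof$hourly[seq_len(24), ]   # one full cycle
    hourly[s, ] <- h$pct[order(h$zt_hour)]
  }
  expect_equal(which.max(colMeans(hourly)) - 1, 13)
})

test_that("startle session honors trivial habituation settings", {
  ga <- two_group_assignment(
    plate_layout(n_rows = 1, n_cols = 2),
    p1 = larva_params(startle_response_prob = 1, habituation_decrement = 1,
                      startle_distance_mean = 2),
    p2 = larva_params(startle_response_prob = 1, habituation_decrement = 1,
                      startle_distance_mean = 2))
  ses <- simulate_startle_session(ga, seed = 3)
  expect_true(all(ses$truth$responder_true))
  # stationary expected distance across trials when decrement = 1
  mu <- ses$expected$gr_mutant$mu
  expect_equal(mu, rep(mu[1], length(mu)))
  expect_equal(mu[1], 2)  # with p = 1 the calibration target is exact
})

test_that("expected distance decays multiplicatively within a block", {
  ga <- group_assignment(one_well_layout(),
                         list(g = larva_params(habituation_decrement = 0.8)))
  ses <- simulate_startle_session(ga, seed = 1)
  mu <- ses$expected$g$mu
  expect_equal(mu[5] / mu[1], 0.8^4)
})

test_that("startle session requires a non-empty assignment", {
  ga <- two_group_assignment()
  empty <- ga[0, ]
  attr(empty, "params") <- attr(ga, "params")
  class(empty) <- class(ga)
  expect_error(simulate_startle_session(empty, seed = 1), "non-empty")
})

test_that("group response rates are recovered near their targets", {
  # single-seed sanity; the multi-seed calibration check lives with the
  # acceptance properties
  ga <- two_group_assignment()
  ses <- simulate_startle_session(ga, seed = 21)
  rate <- tapply(ses$truth$responder_true, ses$truth$group_label, mean) * 100
  expect_lt(abs(rate[["gr_mutant"]] - 62.1), 12)
  expect_lt(abs(rate[["wildtype"]] - 43.1), 12)
})

test_that("rendered frames place the larva blob at the trajectory position", {
  lay <- one_well_layout()
  tr <- still_trajectory(n = 2, x = 0, y = 0)
  rf <- render_frames(list(A1 = tr), lay, pigment_gray_mean = 60,
                      pigment_gray_sd = 0, noise_sd = 0, seed = 1)
  dimg <- subtract_reference(rf$stack$frames[[1]], rf$reference)
  peak <- which(dimg == max(dimg), arr.ind = TRUE)
  ctr <- lay$well_centers_px["A1", ]
  # darkest frame pixel (max difference) within half a pixel of the center
  expect_true(any(abs(peak[, "col"] - 0.5 - ctr$x) <= 0.5 &
                    abs(peak[, "row"] - 0.5 - ctr$y) <= 0.5))
  expect_equal(max(dimg), 200 - 60)
})

test_that("an empty plate renders identical to its reference", {
  lay <- plate_layout(n_rows = 1, n_cols = 2)
  tr <- still_trajectory(n = 2)
  tr$found <- FALSE
  rf <- render_frames(list(A1 = tr), lay, noise_sd = 0, seed = 1)
  expect_identical(rf$stack$frames[[1]], rf$reference)
})

test_that("rendering refuses positions outside the well", {
  lay <- one_well_layout()
  tr <- still_trajectory(n = 2, x = 5, y = 0)  # beyond the 3.5 mm radius
  expect_error(render_frames(list(A1 = tr), lay, seed = 1), "leaves its well")
})

test_that("rendered stacks are seed-deterministic", {
  lay <- one_well_layout()
  ga <- group_assignment(lay, list(g = preset_params("wildtype")))
  pt <- simulate_plate(ga, duration_s = 6, seed = 2)
  a <- render_frames(pt, lay, noise_sd = 2, seed = 9)
  b <- render_frames(pt, lay, noise_sd = 2, seed = 9)
  expect_identical(a, b)
})
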