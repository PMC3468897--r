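test_that("movement flags follow the displacement threshold", {
  tr <- still_trajectory(n = 20)
  expect_false(any(movement_flags(tr)))
  # alternating 0.5 mm jumps against a 0.3 mm threshold
  tr2 <- still_trajectory(n = 20)
  tr2$x_mm <- rep(c(0, 0.5), 10)
  expect_true(all(movement_flags(tr2, 0.3)))
  expect_false(any(movement_flags(tr2, 0.6)))
  expect_error(movement_flags(still_trajectory(n = 1)), "2 samples")
})

test_that("intervals touching a missing position count as not moving", {
  tr <- still_trajectory(n = 5)
  tr$x_mm <- c(0, 1, 2, 3, 4)
  tr$found[3] <- FALSE
  f <- movement_flags(tr, 0.3)
  expect_equal(f, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("percent time in motion uses the per-bin formula", {
  # 900 of 1800 moving frames in one hour -> 50%
  p <- percent_time_in_motion(rep(c(TRUE, FALSE), 900), 0.5, zt0_h = 0)
  expect_equal(p$overall_pct, 50)
  expect_equal(p$hourly$pct, 50)
  expect_equal(p$hourly$n_frames, 1800)
  # never moving -> 0% in every hourly bin
  p0 <- percent_time_in_motion(rep(FALSE, 3600), 0.5, zt0_h = 20)
  expect_true(all(p0$hourly$pct == 0))
  # partial final bin: denominator is the actual frame count
  flags <- c(rep(FALSE, 1800), rep(c(TRUE, rep(FALSE, 9)), 60))
  p2 <- percent_time_in_motion(flags, 0.5, zt0_h = 0)
  last <- nrow(p2$hourly)
  expect_equal(p2$hourly$n_frames[last], 600)
  expect_equal(p2$hourly$pct[last], 10)
})

test_that("raising the movement threshold never increases time in motion", {
  tr <- simulate_trajectory(larva_params(activity_fraction = 0.3),
                            duration_s = 3600, seed = 31)
  pcts <- vapply(c(0.1, 0.3, 0.5, 0.8, 1.2), function(thr)
    percent_time_in_motion(movement_flags(tr, thr), 0.5)$overall_pct,
    numeric(1))
  expect_true(all(diff(pcts) <= 0))
})

test_that("circadian profile finds the peak and flags ties", {
  mk_prof <- function(pct) {
    structure(list(hourly = data.frame(zt_hour = 0:23, pct = pct,
                                       moving_frames = pct * 18,
                                       n_frames = 1800),
                   overall_pct = mean(pct), frames_per_hour = 1800,
                   well_id = "A1"), class = "activity_profile")
  }
  flat <- circadian_profile(mk_prof(rep(5, 24)))
  expect_true(flat$peak_tie)
  expect_equal(flat$peak_zt, 0)
  wave <- circadian_profile(mk_prof(10 + 5 * cos(2 * pi * (0:23 - 13) / 24)))
  expect_false(wave$peak_tie)
  expect_equal(wave$peak_zt, 13)
  # light phase ZT0-14 vs dark ZT14-24 under the 14/10 cycle
  expect_equal(wave$light_mean, mean(wave$hourly_mean$mean_pct[1:14]))
  short <- mk_prof(rep(5, 24))
  short$hourly <- short$hourly[1:6, ]
  expect_error(circadian_profile(short), "24 h")
  expect_silent(circadian_profile(short, partial_ok = TRUE))
})

test_that("simulated larvae are more active in the subjective light phase", {
  p <- preset_params("wildtype")
  hits <- vapply(1:50, function(s) {
    profs <- lapply(1:2, function(i) activity_profile(
      simulate_trajectory(p, duration_s = 24 * 3600, zt_start_h = 20,
                          seed = 1000 * s + i)))
    cp <- circadian_profile(profs)
    cp$light_mean > cp$dark_mean
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("startle measures apply the windowed responder criterion", {
  proto <- startle_protocol()
  # 1.2 mm within 300 ms -> responder; onset on the first step
  seg <- segment_from_steps(c(rep(0.4, 3), rep(0, 97)))
  m <- startle_measures(seg, 0, proto)
  expect_true(m$responder)
  expect_equal(m$distance_mm, 1.2)
  expect_equal(m$latency_ms, 10)
  # 0.9 mm in the first 500 ms but 3 mm overall -> not a responder
  seg2 <- segment_from_steps(c(rep(0.09, 10), rep(0, 40), rep(0.042, 50)))
  m2 <- startle_measures(seg2, 0, proto)
  expect_false(m2$responder)
  expect_equal(m2$distance_mm, 3, tolerance = 1e-9)
  # no movement at all
  m3 <- startle_measures(segment_from_steps(rep(0, 100)), 0, proto)
  expect_equal(m3$distance_mm, 0)
  expect_true(is.na(m3$latency_ms))
  expect_false(m3$responder)
  # truncated window refuses
  expect_error(startle_measures(segment_from_steps(rep(0, 50)), 0, proto),
               "window")
})

test_that("path and net distance readings differ as documented", {
  # out 1 mm and back 1 mm: path 2 mm, net 0
  seg <- segment_from_steps(c(rep(0.2, 5), rep(-0.2, 5), rep(0, 90)))
  proto <- startle_protocol()
  expect_equal(startle_measures(seg, 0, proto)$distance_mm, 2,
               tolerance = 1e-9)
  expect_equal(startle_measures(seg, 0, proto,
                                distance = "net")$distance_mm, 0,
               tolerance = 1e-9)
})

test_that("startle distance is invariant to flipping the y axis", {
  ga <- group_assignment(one_well_layout(),
                         list(g = preset_params("gr_mutant")))
  ses <- simulate_startle_session(ga, seed = 8)
  res <- startle_session_measures(ses$traces, ses$events, ses$protocol)
  flipped <- ses$traces
  flipped$y_mm <- -flipped$y_mm
  res2 <- startle_session_measures(flipped, ses$events, ses$protocol)
  expect_equal(res$distance_mm, res2$distance_mm, tolerance = 1e-12)
})

test_that("inclusion filter retains first-trial responders only", {
  mk <- function(id, resp1) data.frame(
    well_id = id, block = rep(1:5, each = 5), trial = 1:25,
    trial_in_block = rep(1:5, 5),
    responder = c(resp1, rep(TRUE, 24)))
  res <- do.call(rbind, c(lapply(sprintf("W%02d", 1:17), mk, resp1 = TRUE),
                          lapply(sprintf("N%02d", 1:7), mk, resp1 = FALSE)))
  kept <- inclusion_filter(res)
  expect_length(kept, 17)
  expect_true(all(grepl("^W", kept)))
  # nobody responds -> empty with a warning
  res_none <- do.call(rbind, lapply(c("a", "b"), mk, resp1 = FALSE))
  expect_warning(k0 <- inclusion_filter(res_none), "no larva")
  expect_length(k0, 0)
  expect_error(inclusion_filter(res[res$trial != 1, ]), "first trial")
})

test_that("response rate arithmetic is exact", {
  res <- data.frame(well_id = rep(sprintf("w%d", 1:17), each = 1),
                    group_label = "g", trial = 1,
                    responder = c(rep(TRUE, 10), rep(FALSE, 7)))
  rr <- response_rate(res)
  expect_equal(rr$per_trial$pct, 100 * 10 / 17)
  all_resp <- data.frame(well_id = rep(c("a", "b"), 25),
                         group_label = "g",
                         trial = rep(1:25, each = 2), responder = TRUE)
  expect_equal(response_rate(all_resp)$grand$mean_pct, 100)
})

test_that("habituation slopes match exact lines and the OLS oracle", {
  proto <- startle_protocol()
  h <- habituation_slopes(rep(c(5, 4, 3, 2, 1), 5), proto)
  expect_equal(h$per_block_slope, rep(-1, 5))
  expect_equal(habituation_slopes(rep(2, 25), proto)$overall_slope, 0)
  # normal-equations oracle on random data
  set.seed(77)
  y <- rnorm(25)
  h2 <- habituation_slopes(y, proto)
  ne_slope <- function(x, y) {
    X <- cbind(1, x)
    solve(t(X) %*% X, t(X) %*% y)[2]
  }
  expect_equal(h2$overall_slope, ne_slope(1:25, y), tolerance = 1e-10)
  for (b in 1:5)
    expect_equal(h2$per_block_slope[b],
                 ne_slope(1:5, y[(b - 1) * 5 + 1:5]), tolerance = 1e-10)
  expect_error(habituation_slopes(y[1:10], proto), "per trial")
})

test_that("simulated habituating sessions yield negative slopes", {
  lay <- plate_layout(n_rows = 2, n_cols = 4)
  ga <- group_assignment(lay, list(
    g = larva_params(startle_response_prob = 1, habituation_decrement = 0.8,
                     startle_distance_mean = 2.3)))
  neg <- vapply(1:40, function(s) {
    ses <- simulate_startle_session(ga, seed = 5000 + s)
    res <- startle_session_measures(ses$traces, ses$events, ses$protocol)
    mean(habituation_slopes(trial_means(res),
                            ses$protocol)$per_block_slope) < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
})
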