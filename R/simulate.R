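#' Simulate a spontaneous-activity trajectory for one larva
#'
#' Generates a ground-truth swimming trajectory inside a circular well,
#' sampled at the video acquisition rate. Locomotion is modeled as discrete
#' swim bouts arriving as a Poisson process whose rate is modulated
#' sinusoidally over the 24 h circadian cycle; each bout displaces the larva
#' by a shifted-exponential distance in a uniformly random direction, with
#' billiard reflection at the well wall.
#'
#' When `params$activity_fraction` is set, the per-interval bout rate is
#' derived so that the expected fraction of frame intervals containing at
#' least one bout equals `activity_fraction` averaged over a full cycle
#' (modulated by `circadian_amplitude` with the maximal hourly bin at
#' `circadian_peak_zt`). Since every bout displaces the larva by at least
#' `bout_min_mm`, that fraction is what a downstream movement threshold
#' below `bout_min_mm` recovers as percent time in motion.
#'
#' @param params A [larva_params()] object.
#' @param duration_s Recording duration in seconds (> 0).
#' @param frame_rate_hz Acquisition rate in Hz (> 0); 0.5 Hz in the standard
#'   spontaneous-activity assay.
#' @param well_radius_mm Radius of the well confining the larva (mm).
#' @param wall_margin_mm Body half-width kept clear of the wall: the
#'   centroid is confined to `well_radius_mm - wall_margin_mm` because a
#'   larva's center of mass cannot reach the glass.
#' @param zt_start_h Zeitgeber time (h) of the first frame.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @param well_id Label stored with the trajectory.
#'
#' @return A data frame of class `trajectory` with columns `frame` (0-based),
#'   `t_s`, `zt_h`, `x_mm`, `y_mm` (well-centered), `found` (all `TRUE` for
#'   simulated data) and `moving` (ground-truth flag: >= 1 bout in the
#'   interval ending at that frame), plus attributes `well_id`,
#'   `frame_rate_hz`, `t0_zt_h` and `well_radius_mm`.
#' @examples
#' tr <- simulate_trajectory(larva_params(activity_fraction = 0.2),
#'                           duration_s = 600, seed = 1)
#' mean(tr$moving[-1])
#' @export
simulate_trajectory <- function(params, duration_s, frame_rate_hz = 0.5,
                                well_radius_mm = 3.5, wall_margin_mm = 0.35,
                                zt_start_h = 20, seed = NULL,
                                well_id = "A1") {
  validate_larva_params(params)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r_eff <- max(well_radius_mm - wall_margin_mm, 0.5 * well_radius_mm)
  n_frames <- max(1L, as.integer(round(duration_s * frame_rate_hz)))
  dt <- 1 / frame_rate_hz
  t_s <- (seq_len(n_frames) - 1) * dt
  zt <- (zt_start_h + t_s / 3600) %% 24
  lambda <- c(0, .bout_lambda(params, zt[-1], dt))
  # random start anywhere in the inner half of the well
  r0 <- well_radius_mm * 0.5 * sqrt(runif(1))
  th0 <- runif(1, 0, 2 * pi)
  mean_excess <- max(params$bout_displacement_mean - params$bout_min_mm, 1e-6)
  walk <- cpp_bout_walk(n_frames, lambda, params$bout_min_mm, mean_excess,
                        r0 * cos(th0), r0 * sin(th0), r_eff)
  out <- data.frame(
    frame = seq_len(n_frames) - 1L,
    t_s = t_s, zt_h = zt,
    x_mm = walk$x, y_mm = walk$y,
    found = TRUE,
    moving = walk$n_bouts > 0L
  )
  structure(out, well_id = well_id, frame_rate_hz = frame_rate_hz,
            t0_zt_h = zt_start_h, well_radius_mm = well_radius_mm,
            class = c("trajectory", "data.frame"))
}

# Relative activity drive over the circadian cycle: a sinusoid peaking at
# the center of the circadian_peak_zt hourly bin (peak_zt + 0.5, so that
# bin is maximal) multiplied by a subjective light-phase mask (activity
# elevated during ZT 0-14, suppressed during ZT 14-24 under the 14/10
# cycle), normalized to mean 1 over a full cycle so the activity-fraction
# calibration is unchanged.
.circadian_weight <- function(params, zt) {
  w <- (1 + params$circadian_amplitude *
          cos(2 * pi * (zt - (params$circadian_peak_zt + 0.5)) / 24))
  b <- params$light_phase_boost
  w <- w * ifelse(zt < 14, 1 + b, 1 - b * 14 / 10)
  grid <- seq(0, 24, length.out = 2881)[-2881]
  wg <- (1 + params$circadian_amplitude *
           cos(2 * pi * (grid - (params$circadian_peak_zt + 0.5)) / 24)) *
    ifelse(grid < 14, 1 + b, 1 - b * 14 / 10)
  w / mean(wg)
}

# Per-interval Poisson bout mean.
.bout_lambda <- function(params, zt, dt) {
  w <- .circadian_weight(params, zt)
  if (!is.na(params$activity_fraction)) {
    f <- pmin(pmax(params$activity_fraction * w, 0), 0.999)
    -log(1 - f)
  } else {
    pmax(params$bout_rate / 60 * dt * w, 0)
  }
}

#' Simulate spontaneous activity for a whole plate
#'
#' Runs [simulate_trajectory()] for every assigned well of a plate under a
#' single seed (one RNG stream, wells in plate order, so the full plate is
#' reproducible).
#'
#' @param assignment A [group_assignment()].
#' @param duration_s,frame_rate_hz,zt_start_h As in [simulate_trajectory()].
#' @param well_radius_mm Well radius (mm); defaults to 3.5 (7 mm wells).
#' @param seed Integer seed for the plate.
#' @return A named list of `trajectory` objects (one per assigned well), of
#'   class `plate_trajectories`, with the assignment in attribute
#'   `assignment`.
#' @export
simulate_plate <- function(assignment, duration_s, frame_rate_hz = 0.5,
                           zt_start_h = 20, well_radius_mm = 3.5,
                           seed = NULL) {
  stopifnot(inherits(assignment, "group_assignment"))
  if (!is.null(seed)) set.seed(seed)
  params <- attr(assignment, "params")
  out <- vector("list", nrow(assignment))
  names(out) <- assignment$well_id
  for (i in seq_len(nrow(assignment))) {
    out[[i]] <- simulate_trajectory(
      params[[assignment$group_label[i]]], duration_s = duration_s,
      frame_rate_hz = frame_rate_hz, well_radius_mm = well_radius_mm,
      zt_start_h = zt_start_h, seed = NULL,
      well_id = assignment$well_id[i])
  }
  structure(out, assignment = assignment,
            class = c("plate_trajectories", "list"))
}

#' Tap-startle stimulus protocol
#'
#' The standard auditory-startle protocol: blocks of consecutive tap trials
#' separated by long rests. Defaults give 5 blocks of 5 trials with 2 s
#' between taps and 30 min between blocks — 25 trials over 150 min — with
#' movement filmed at 100 Hz for 1 s after each tap.
#'
#' @param trials_per_block,n_blocks Trial structure.
#' @param inter_trial_s Seconds between taps within a block.
#' @param inter_block_min Minutes between block onsets' rest period.
#' @param post_stim_window_s Analyzed window after each tap (s).
#' @param frame_rate_hz Startle video rate (Hz).
#' @return An object of class `startle_protocol`.
#' @examples
#' p <- startle_protocol()
#' nrow(stim_events(p))  # 25
#' @export
startle_protocol <- function(trials_per_block = 5, n_blocks = 5,
                             inter_trial_s = 2, inter_block_min = 30,
                             post_stim_window_s = 1, frame_rate_hz = 100) {
  vals <- c(trials_per_block, n_blocks, inter_trial_s, inter_block_min,
            post_stim_window_s, frame_rate_hz)
  if (any(vals <= 0)) stop("all protocol fields must be positive",
                           call. = FALSE)
  structure(list(trials_per_block = as.integer(trials_per_block),
                 n_blocks = as.integer(n_blocks),
                 inter_trial_s = inter_trial_s,
                 inter_block_min = inter_block_min,
                 post_stim_window_s = post_stim_window_s,
                 frame_rate_hz = frame_rate_hz),
            class = "startle_protocol")
}

#' Stimulus event log for a protocol
#'
#' @param protocol A [startle_protocol()].
#' @return Data frame with columns `trial` (global 1..n), `block`,
#'   `trial_in_block` and `t_s` (tap time from session start).
#' @export
stim_events <- function(protocol) {
  stopifnot(inherits(protocol, "startle_protocol"))
  b <- rep(seq_len(protocol$n_blocks), each = protocol$trials_per_block)
  j <- rep(seq_len(protocol$trials_per_block), times = protocol$n_blocks)
  t_s <- (b - 1) * protocol$inter_block_min * 60 +
    (j - 1) * protocol$inter_trial_s
  data.frame(trial = seq_along(b), block = b, trial_in_block = j, t_s = t_s)
}

# Expected distance of sub-criterion (non-responder) movement: half the
# trials are still, the rest drift uniformly between 0.05 and 0.9 mm.
.NONRESP_STILL_PROB <- 0.5
.NONRESP_RANGE <- c(0.05, 0.9)
.RESPONDER_MIN_MM <- 1.4   # floor guaranteeing the >1 mm / 500 ms criterion

# Solve the trial-1 responder mean ("base") so that the expected group-mean
# distance over all trials of larvae retained by the first-trial inclusion
# filter equals the calibration target. Within a block the responder mean
# decays multiplicatively: mu_j = base * dec^(j-1).
.startle_base <- function(target, p, dec, trials_per_block, n_blocks) {
  mu_nr <- (1 - .NONRESP_STILL_PROB) * mean(.NONRESP_RANGE)
  W <- sum(dec^(seq_len(trials_per_block) - 1))
  n_t <- trials_per_block * n_blocks
  if (p <= 0) return(max(target, .RESPONDER_MIN_MM + 0.05))
  base <- (n_t * target - (1 - p) * mu_nr * (n_t - 1)) /
    (1 + p * (n_blocks * W - 1))
  max(base, .RESPONDER_MIN_MM + 0.05)
}

#' Simulate a tap-startle session with ground truth
#'
#' Draws, for every assigned larva and every trial, a responder status
#' (Bernoulli with the group's `startle_response_prob`) and a 1 s
#' post-stimulus swim. Responder distances decay multiplicatively within a
#' block by `habituation_decrement`; the trial-1 responder mean is solved so
#' the expected mean distance over the analyzed (inclusion-filtered) trials
#' equals `startle_distance_mean`. Swims are rendered as 100 Hz paths with a
#' fast initial burst (the C-bend and early rapid swim, ~0.4 mm per 10 ms
#' step) carrying the first ~1.2 mm, the remainder tapering off over the
#' rest of the second — so onset-latency measures are exercised.
#'
#' @param assignment A [group_assignment()].
#' @param protocol A [startle_protocol()].
#' @param well_radius_mm Well radius (mm).
#' @param wall_margin_mm Body half-width kept clear of the wall.
#' @param seed Integer seed.
#' @return An object of class `startle_session`: list with `events` (the
#'   stimulus log), `truth` (per well x trial: `responder_true`,
#'   `distance_true`, `latency_true_ms`), `traces` (long data frame of
#'   100 Hz positions for each 1 s window: `well_id`, `block`, `trial`,
#'   `frame` 0..100, `t_s`, `x_mm`, `y_mm`), the protocol, and per-group
#'   calibration in `expected` (trial-level responder means).
#' @examples
#' ga <- group_assignment(plate_layout(n_rows = 1, n_cols = 2),
#'                        list(wt = preset_params("wildtype")))
#' s <- simulate_startle_session(ga, startle_protocol(), seed = 1)
#' head(s$truth)
#' @export
simulate_startle_session <- function(assignment, protocol = startle_protocol(),
                                     well_radius_mm = 3.5,
                                     wall_margin_mm = 0.35, seed = NULL) {
  stopifnot(inherits(protocol, "startle_protocol"))
  if (!inherits(assignment, "group_assignment") || nrow(assignment) == 0)
    stop("assignment must be a non-empty group_assignment", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  params <- attr(assignment, "params")
  events <- stim_events(protocol)
  n_t <- nrow(events)
  fr <- protocol$frame_rate_hz
  r_eff <- max(well_radius_mm - wall_margin_mm, 0.5 * well_radius_mm)
  n_steps <- as.integer(round(protocol$post_stim_window_s * fr))

  expected <- lapply(params, function(p) {
    base <- .startle_base(p$startle_distance_mean, p$startle_response_prob,
                          p$habituation_decrement, protocol$trials_per_block,
                          protocol$n_blocks)
    list(base = base,
         mu = base * p$habituation_decrement^
           (seq_len(protocol$trials_per_block) - 1))
  })

  truth <- vector("list", nrow(assignment))
  traces <- vector("list", nrow(assignment))
  for (i in seq_len(nrow(assignment))) {
    wid <- assignment$well_id[i]
    grp <- assignment$group_label[i]
    p <- params[[grp]]
    mu <- expected[[grp]]$mu
    resp <- rbinom(n_t, 1, p$startle_response_prob) == 1
    dist <- numeric(n_t)
    lat_ms <- rep(NA_real_, n_t)
    tr_x <- matrix(0, nrow = n_t, ncol = n_steps + 1)
    tr_y <- matrix(0, nrow = n_t, ncol = n_steps + 1)
    # larva sits somewhere in the inner well at each tap
    for (k in seq_len(n_t)) {
      r0 <- r_eff * 0.6 * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      x0 <- r0 * cos(th); y0 <- r0 * sin(th)
      j <- events$trial_in_block[k]
      if (resp[k]) {
        me <- max(mu[j] - .RESPONDER_MIN_MM, 0.05)
        s_j <- max(p$startle_distance_sd *
                     p$habituation_decrement^(j - 1), 0.05)
        d <- .RESPONDER_MIN_MM + rgamma(1, shape = (me / s_j)^2,
                                        scale = s_j^2 / me)
      } else if (runif(1) < .NONRESP_STILL_PROB) {
        d <- 0
      } else {
        d <- runif(1, .NONRESP_RANGE[1], .NONRESP_RANGE[2])
      }
      dist[k] <- d
      steps <- numeric(n_steps)
      if (d > 0) {
        l0 <- sample(2:12, 1)               # onset 20-120 ms post-tap
        lat_ms[k] <- l0 * 1000 / fr
        db <- min(d, 1.2)
        nb <- max(1L, as.integer(ceiling(db / 0.4)))
        burst_idx <- l0:min(l0 + nb - 1, n_steps)
        steps[burst_idx] <- db / length(burst_idx)
        rem <- d - db
        if (rem > 0 && l0 + nb <= n_steps) {
          idx <- (l0 + nb):n_steps
          wgt <- exp(-(seq_along(idx)) / 20)
          steps[idx] <- rem * wgt / sum(wgt)
        }
        path <- cpp_swim_path(steps, x0, y0, runif(1, 0, 2 * pi),
                              0.15, r_eff)
        tr_x[k, ] <- c(x0, path$x); tr_y[k, ] <- c(y0, path$y)
      } else {
        tr_x[k, ] <- x0; tr_y[k, ] <- y0
      }
    }
    truth[[i]] <- data.frame(
      well_id = wid, group_label = grp,
      block = events$block, trial = events$trial,
      trial_in_block = events$trial_in_block,
      responder_true = resp, distance_true = dist,
      latency_true_ms = lat_ms, stringsAsFactors = FALSE)
    traces[[i]] <- data.frame(
      well_id = wid,
      block = rep(events$block, each = n_steps + 1),
      trial = rep(events$trial, each = n_steps + 1),
      frame = rep(0:n_steps, times = n_t),
      t_s = rep(events$t_s, each = n_steps + 1) +
        rep(0:n_steps, times = n_t) / fr,
      x_mm = as.vector(t(tr_x)), y_mm = as.vector(t(tr_y)),
      stringsAsFactors = FALSE)
  }
  structure(list(events = events,
                 truth = do.call(rbind, truth),
                 traces = do.call(rbind, traces),
                 protocol = protocol,
                 expected = expected,
                 assignment = assignment),
            class = "startle_session")
}

#' @export
print.startle_session <- function(x, ...) {
  cat(sprintf("Startle session: %d larvae, %d blocks x %d trials (%d taps)\n",
              length(unique(x$truth$well_id)), x$protocol$n_blocks,
              x$protocol$trials_per_block, nrow(x$events)))
  cat(sprintf("  ground-truth response rate: %.1f%%\n",
              100 * mean(x$truth$responder_true)))
  invisible(x)
}
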