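#' Frame-to-frame movement flags
#'
#' Marks each inter-frame interval of a trajectory as moving when the
#' centroid displaced by more than the threshold between consecutive frames
#' (a 2 s interval at the standard 0.5 Hz acquisition). Intervals touching a
#' missing position count as not moving.
#'
#' @param traj A `trajectory` data frame (>= 2 samples).
#' @param displacement_threshold_mm Movement threshold (mm); the 0.3 mm
#'   default sits above centroid jitter and below a minimal swim bout.
#' @return Logical vector of length `nrow(traj) - 1`.
#' @examples
#' tr <- simulate_trajectory(larva_params(), duration_s = 60, seed = 1)
#' mean(movement_flags(tr))
#' @export
movement_flags <- function(traj, displacement_threshold_mm = 0.3) {
  if (nrow(traj) < 2)
    stop("trajectory needs at least 2 samples", call. = FALSE)
  dx <- diff(traj$x_mm); dy <- diff(traj$y_mm)
  disp <- sqrt(dx^2 + dy^2)
  ok <- traj$found[-1] & traj$found[-nrow(traj)]
  flags <- !is.na(disp) & disp > displacement_threshold_mm
  flags & ok
}

#' Percent time in motion per ZT hour
#'
#' Bins movement flags into zeitgeber-hour bins and expresses activity as
#' the percentage of frame intervals with movement in each bin (1800 frames
#' per full hour at 0.5 Hz). Partial bins at the recording edges use their
#' actual interval count as denominator.
#'
#' @param flags Logical vector from [movement_flags()] (interval `i` ends at
#'   frame `i`, i.e. at time `i / frame_rate_hz`).
#' @param frame_rate_hz Acquisition rate (Hz).
#' @param zt0_h Zeitgeber time (h) of frame 0.
#' @param well_id Optional label carried into the result.
#' @return An object of class `activity_profile`: list with `hourly`
#'   (data frame `zt_hour`, `pct`, `moving_frames`, `n_frames`, in
#'   recording order), `overall_pct`, `frames_per_hour` and `well_id`.
#' @examples
#' prof <- percent_time_in_motion(rep(c(TRUE, FALSE), 900), 0.5, zt0_h = 20)
#' prof$overall_pct
#' @export
percent_time_in_motion <- function(flags, frame_rate_hz, zt0_h = 0,
                                   well_id = NA_character_) {
  if (length(flags) == 0) stop("no movement flags", call. = FALSE)
  # bin each interval by its midpoint so an interval ending exactly on an
  # hour boundary still belongs to the hour it occupies
  t_mid <- (seq_along(flags) - 0.5) / frame_rate_hz
  h_abs <- floor(zt0_h + t_mid / 3600)
  bins <- unique(h_abs)
  moving <- vapply(bins, function(b) sum(flags[h_abs == b]), numeric(1))
  total <- vapply(bins, function(b) sum(h_abs == b), numeric(1))
  structure(list(
    hourly = data.frame(zt_hour = bins %% 24,
                        pct = 100 * moving / total,
                        moving_frames = moving, n_frames = total),
    overall_pct = 100 * sum(flags) / length(flags),
    frames_per_hour = frame_rate_hz * 3600,
    well_id = well_id), class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("Activity profile%s: %.2f%% of frames in motion over %d hourly bins\n",
              if (is.na(x$well_id)) "" else paste0(" (", x$well_id, ")"),
              x$overall_pct, nrow(x$hourly)))
  invisible(x)
}

#' Activity profile of a trajectory
#'
#' Convenience wrapper chaining [movement_flags()] and
#' [percent_time_in_motion()].
#'
#' @inheritParams movement_flags
#' @return An `activity_profile`.
#' @export
activity_profile <- function(traj, displacement_threshold_mm = 0.3) {
  fr <- attr(traj, "frame_rate_hz")
  percent_time_in_motion(
    movement_flags(traj, displacement_threshold_mm),
    frame_rate_hz = fr,
    zt0_h = if (is.null(attr(traj, "t0_zt_h"))) traj$zt_h[1]
            else attr(traj, "t0_zt_h"),
    well_id = attr(traj, "well_id"))
}

#' Circadian activity profile of a group
#'
#' Averages hourly activity across larvae and locates the circadian peak.
#' Phase means follow the 14/10 light/dark entrainment cycle: subjective
#' light is ZT 0-14, subjective dark ZT 14-24.
#'
#' @param profiles List of `activity_profile` objects (one per larva).
#' @param partial_ok Accept recordings covering fewer than 24 distinct ZT
#'   hours (phase means are then computed over the covered bins).
#' @return An object of class `circadian_profile`: `hourly_mean` (data
#'   frame `zt_hour`, `mean_pct`), `peak_zt` (ZT hour of the maximal mean
#'   bin; ties resolved to the smallest ZT hour), `peak_tie` flag,
#'   `light_mean` and `dark_mean`.
#' @export
circadian_profile <- function(profiles, partial_ok = FALSE) {
  if (inherits(profiles, "activity_profile")) profiles <- list(profiles)
  if (length(profiles) == 0) stop("no profiles", call. = FALSE)
  hr <- do.call(rbind, lapply(profiles, function(p) p$hourly))
  agg <- stats::aggregate(cbind(moving_frames, n_frames) ~ zt_hour,
                          data = hr, FUN = sum)
  agg$mean_pct <- 100 * agg$moving_frames / agg$n_frames
  agg <- agg[order(agg$zt_hour), c("zt_hour", "mean_pct")]
  if (nrow(agg) < 24 && !partial_ok)
    stop("need a full 24 h of hourly bins (or partial_ok = TRUE)",
         call. = FALSE)
  mx <- max(agg$mean_pct)
  at_max <- agg$zt_hour[agg$mean_pct == mx]
  light <- agg$zt_hour >= 0 & agg$zt_hour < 14
  structure(list(hourly_mean = agg,
                 peak_zt = min(at_max),
                 peak_tie = length(at_max) > 1,
                 light_mean = mean(agg$mean_pct[light]),
                 dark_mean = mean(agg$mean_pct[!light])),
            class = "circadian_profile")
}

#' @export
print.circadian_profile <- function(x, ...) {
  cat(sprintf("Circadian profile: peak at ZT%g%s; light-phase mean %.2f%%, dark-phase mean %.2f%%\n",
              x$peak_zt, if (x$peak_tie) " (tied)" else "",
              x$light_mean, x$dark_mean))
  invisible(x)
}

#' Startle measurements for one trial
#'
#' Quantifies the 1 s post-stimulus swim from a 100 Hz trajectory segment:
#' distance is the summed path length over the window (set
#' `distance = "net"` for straight-line displacement instead), latency is
#' the time of the first inter-frame step exceeding the onset threshold,
#' and responder status applies the >1 mm cumulative movement within 500 ms
#' criterion.
#'
#' @param segment Trajectory data frame covering
#'   `[stim_t, stim_t + post_stim_window_s]` at the protocol frame rate.
#' @param stim_t Tap time (s) on the segment's clock.
#' @param protocol A [startle_protocol()].
#' @param criterion_mm,criterion_window_s Responder criterion: cumulative
#'   movement (mm, strict) within the window (s) post-stimulus.
#' @param latency_threshold_mm Per-step onset threshold (mm).
#' @param distance `"path"` (default) or `"net"`.
#' @return One-row data frame: `distance_mm`, `latency_ms`, `responder`.
#' @export
startle_measures <- function(segment, stim_t, protocol = startle_protocol(),
                             criterion_mm = 1, criterion_window_s = 0.5,
                             latency_threshold_mm = 0.3,
                             distance = c("path", "net")) {
  distance <- match.arg(distance)
  win <- protocol$post_stim_window_s
  tol <- 1e-9
  seg <- segment[segment$t_s >= stim_t - tol &
                   segment$t_s <= stim_t + win + tol, , drop = FALSE]
  n_expect <- round(win * protocol$frame_rate_hz) + 1
  if (nrow(seg) < n_expect)
    stop("segment does not cover the post-stimulus window", call. = FALSE)
  seg <- seg[order(seg$t_s), ]
  steps <- sqrt(diff(seg$x_mm)^2 + diff(seg$y_mm)^2)
  t_step <- seg$t_s[-1] - stim_t
  dist_mm <- if (distance == "path") sum(steps) else
    sqrt((seg$x_mm[nrow(seg)] - seg$x_mm[1])^2 +
         (seg$y_mm[nrow(seg)] - seg$y_mm[1])^2)
  cum_in_win <- sum(steps[t_step <= criterion_window_s + tol])
  onset <- which(steps > latency_threshold_mm)
  data.frame(
    distance_mm = dist_mm,
    latency_ms = if (length(onset)) t_step[onset[1]] * 1000 else NA_real_,
    responder = cum_in_win > criterion_mm)
}

#' Startle measurements for a whole session
#'
#' Applies [startle_measures()] to every larva x trial of a simulated or
#' tracked startle session.
#'
#' @param traces Long data frame of 100 Hz positions (`well_id`, `trial`,
#'   `t_s`, `x_mm`, `y_mm`), e.g. `session$traces`.
#' @param events Stimulus log ([stim_events()] format).
#' @param groups Optional data frame `well_id`, `group_label` to merge in.
#' @inheritParams startle_measures
#' @return Data frame with one row per larva x trial: `well_id`,
#'   `group_label` (if given), `block`, `trial`, `trial_in_block`,
#'   `distance_mm`, `latency_ms`, `responder`.
#' @export
startle_session_measures <- function(traces, events,
                                     protocol = startle_protocol(),
                                     groups = NULL, ...) {
  out <- list()
  for (wid in unique(traces$well_id)) {
    tw <- traces[traces$well_id == wid, ]
    for (k in seq_len(nrow(events))) {
      seg <- tw[tw$trial == events$trial[k], ]
      m <- startle_measures(seg, stim_t = events$t_s[k],
                            protocol = protocol, ...)
      out[[length(out) + 1]] <- data.frame(
        well_id = wid, block = events$block[k], trial = events$trial[k],
        trial_in_block = events$trial_in_block[k], m,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(groups))
    res$group_label <- groups$group_label[match(res$well_id, groups$well_id)]
  res
}

#' First-trial inclusion filter
#'
#' A larva enters the startle analysis only if it met the responder
#' criterion on the first trial of the first block; all 25 trials of
#' retained larvae are kept.
#'
#' @param results Per-trial results (from [startle_session_measures()]);
#'   must contain block-1/trial-1 rows for every larva.
#' @return Character vector of retained well ids.
#' @export
inclusion_filter <- function(results) {
  first <- results[results$block == 1 & results$trial_in_block == 1, ]
  all_ids <- unique(results$well_id)
  if (!setequal(first$well_id, all_ids))
    stop("missing first trial for some larvae", call. = FALSE)
  kept <- first$well_id[first$responder]
  if (length(kept) == 0)
    warning("no larva met the first-trial response criterion")
  kept
}

#' Per-trial group response rate
#'
#' Percentage of each group meeting the responder criterion on each trial,
#' plus the grand mean across trials.
#'
#' @param results Per-trial results with `group_label` and `responder`
#'   columns (normally after [inclusion_filter()]).
#' @return An object of class `response_rate`: `per_trial` (data frame
#'   `group_label`, `trial`, `pct`, `n`) and `grand` (data frame
#'   `group_label`, `mean_pct`, `sd_pct`, `n_trials`).
#' @export
response_rate <- function(results) {
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  if (is.null(results$group_label)) results$group_label <- "all"
  per <- stats::aggregate(responder ~ group_label + trial, data = results,
                          FUN = function(z) 100 * mean(z))
  names(per)[names(per) == "responder"] <- "pct"
  nn <- stats::aggregate(responder ~ group_label + trial, data = results,
                         FUN = length)
  per$n <- nn$responder
  per <- per[order(per$group_label, per$trial), ]
  grand <- do.call(rbind, lapply(split(per, per$group_label), function(d)
    data.frame(group_label = d$group_label[1], mean_pct = mean(d$pct),
               sd_pct = sd(d$pct), n_trials = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(grand) <- NULL
  structure(list(per_trial = per, grand = grand), class = "response_rate")
}

#' @export
print.response_rate <- function(x, ...) {
  cat("Group response rate (% responding, mean over trials):\n")
  for (i in seq_len(nrow(x$grand)))
    cat(sprintf("  %s: %.1f%% (sd %.1f over %d trials)\n",
                x$grand$group_label[i], x$grand$mean_pct[i],
                x$grand$sd_pct[i], x$grand$n_trials[i]))
  invisible(x)
}

#' Habituation slopes
#'
#' Startle habituation summarized as the ordinary-least-squares slope of
#' mean response distance against trial number: one slope per block
#' (through its 5 trials) and one overall slope across all 25 trials.
#'
#' @param distances Numeric vector of group-mean distances in global trial
#'   order (length = total trials of the protocol).
#' @param protocol A [startle_protocol()].
#' @param group_label Optional label carried into the result.
#' @return An object of class `habituation_result`: `per_block_slope`
#'   (mm/trial, one per block), `overall_slope` (mm/trial) and
#'   `group_label`.
#' @examples
#' habituation_slopes(rep(c(5, 4, 3, 2, 1), 5))$per_block_slope
#' @export
habituation_slopes <- function(distances, protocol = startle_protocol(),
                               group_label = NA_character_) {
  k <- protocol$trials_per_block
  nb <- protocol$n_blocks
  if (length(distances) != k * nb)
    stop("need one mean distance per trial", call. = FALSE)
  if (k * nb < 2 || k < 2)
    stop("fewer than 2 trials", call. = FALSE)
  if (any(!is.finite(distances)))
    stop("distances must be finite", call. = FALSE)
  ols_slope <- function(x, y) {
    xc <- x - mean(x)
    sum(xc * y) / sum(xc^2)
  }
  per_block <- vapply(seq_len(nb), function(b) {
    idx <- ((b - 1) * k + 1):(b * k)
    ols_slope(seq_len(k), distances[idx])
  }, numeric(1))
  structure(list(per_block_slope = per_block,
                 overall_slope = ols_slope(seq_along(distances), distances),
                 group_label = group_label),
            class = "habituation_result")
}

#' @export
print.habituation_result <- function(x, ...) {
  cat(sprintf("Habituation slopes%s (mm/trial): blocks %s; overall %.3f\n",
              if (is.na(x$group_label)) "" else paste0(" [", x$group_label, "]"),
              paste(sprintf("%.3f", x$per_block_slope), collapse = ", "),
              x$overall_slope))
  invisible(x)
}

#' Group-mean distance per trial
#'
#' @param results Per-trial results with `trial` and `distance_mm`.
#' @return Numeric vector of mean distance in global trial order.
#' @export
trial_means <- function(results) {
  agg <- stats::aggregate(distance_mm ~ trial, data = results, FUN = mean)
  agg$distance_mm[order(agg$trial)]
}
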