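#' Behavioral parameters for a simulated larva
#'
#' Bundles the tunable quantities that drive the synthetic-data generator:
#' spontaneous bout locomotion with a circadian rhythm, tap-evoked startle
#' swims with within-block habituation, and rendered dorsal pigmentation.
#'
#' @param activity_fraction Target fraction of sampled frame intervals in
#'   which the larva moves (0-1), averaged over a full circadian cycle. At
#'   the default 0.5 Hz acquisition this is the expected "percent time in
#'   motion"/100. If `NA`, the bout rate is taken from `bout_rate` instead.
#' @param bout_rate Expected swim bouts per minute. Only used when
#'   `activity_fraction` is `NA`; otherwise the Poisson bout rate is derived
#'   from `activity_fraction` and the acquisition rate.
#' @param bout_displacement_mean Mean displacement per swim bout (mm). Bout
#'   displacements are shifted-exponential with a floor of `bout_min_mm` so
#'   that a frame containing a bout registers as movement.
#' @param bout_min_mm Minimum per-bout displacement (mm); must exceed the
#'   downstream movement threshold for calibration to be exact.
#' @param circadian_amplitude Relative modulation depth of the activity
#'   rhythm (0-1); 0 disables the rhythm.
#' @param circadian_peak_zt Zeitgeber hour (in `[0, 24)`) of the maximal
#'   hourly activity bin. The underlying sinusoid peaks at the center of
#'   that bin (`circadian_peak_zt + 0.5` h) so the bin itself is maximal.
#' @param light_phase_boost Relative elevation of activity during the
#'   subjective light phase (ZT 0-14 of the 14/10 entrainment cycle), with
#'   the dark phase suppressed correspondingly; the full circadian weight
#'   is renormalized so the cycle-average activity stays at
#'   `activity_fraction`. 0 disables light/dark masking.
#' @param startle_distance_mean Expected group-mean distance (mm) traveled in
#'   the 1 s post-stimulus window, averaged over the analyzed trials of a
#'   session (after first-trial inclusion filtering).
#' @param startle_distance_sd Spread (mm) of responder startle distances.
#' @param startle_response_prob Per-trial probability of meeting the
#'   responder criterion (>1 mm within 500 ms post-stimulus).
#' @param habituation_decrement Per-trial multiplicative decay of expected
#'   startle distance within a block, in (0, 1]; 1 disables habituation.
#' @param pigment_gray_mean,pigment_gray_sd 8-bit grayscale intensity
#'   (0-255) of the rendered larva body; each larva draws one body value
#'   from this normal distribution.
#'
#' @return An object of class `larva_params` (a validated list).
#' @examples
#' p <- larva_params(activity_fraction = 0.095)
#' p$circadian_peak_zt
#' @seealso [preset_params()] for ready-made genotype/treatment calibrations.
#' @export
larva_params <- function(activity_fraction = 0.095,
                         bout_rate = 3,
                         bout_displacement_mean = 1.0,
                         bout_min_mm = 0.4,
                         circadian_amplitude = 0.5,
                         circadian_peak_zt = 13,
                         light_phase_boost = 0.2,
                         startle_distance_mean = 1.5,
                         startle_distance_sd = 2.2,
                         startle_response_prob = 0.431,
                         habituation_decrement = 0.8,
                         pigment_gray_mean = 82.91,
                         pigment_gray_sd = 13.31) {
  p <- list(
    activity_fraction = activity_fraction,
    bout_rate = bout_rate,
    bout_displacement_mean = bout_displacement_mean,
    bout_min_mm = bout_min_mm,
    circadian_amplitude = circadian_amplitude,
    circadian_peak_zt = circadian_peak_zt,
    light_phase_boost = light_phase_boost,
    startle_distance_mean = startle_distance_mean,
    startle_distance_sd = startle_distance_sd,
    startle_response_prob = startle_response_prob,
    habituation_decrement = habituation_decrement,
    pigment_gray_mean = pigment_gray_mean,
    pigment_gray_sd = pigment_gray_sd
  )
  validate_larva_params(p)
  structure(p, class = "larva_params")
}

validate_larva_params <- function(p) {
  in01 <- function(x) !is.na(x) && x >= 0 && x <= 1
  if (!is.na(p$activity_fraction) && !in01(p$activity_fraction))
    stop("activity_fraction must be in [0, 1]", call. = FALSE)
  if (!in01(p$startle_response_prob))
    stop("startle_response_prob must be in [0, 1]", call. = FALSE)
  if (!in01(p$circadian_amplitude))
    stop("circadian_amplitude must be in [0, 1]", call. = FALSE)
  if (p$circadian_peak_zt < 0 || p$circadian_peak_zt >= 24)
    stop("circadian_peak_zt must be in [0, 24)", call. = FALSE)
  if (is.null(p$light_phase_boost) || p$light_phase_boost < 0 ||
      p$light_phase_boost > 0.7)
    stop("light_phase_boost must be in [0, 0.7]", call. = FALSE)
  if (p$bout_displacement_mean < 0 || p$startle_distance_mean < 0 ||
      p$bout_min_mm < 0)
    stop("displacements must be >= 0", call. = FALSE)
  if (p$habituation_decrement <= 0 || p$habituation_decrement > 1)
    stop("habituation_decrement must be in (0, 1]", call. = FALSE)
  if (p$pigment_gray_mean < 0 || p$pigment_gray_mean > 255)
    stop("pigment_gray_mean must be an 8-bit intensity in [0, 255]",
         call. = FALSE)
  invisible(p)
}

#' @export
print.larva_params <- function(x, ...) {
  cat("Larva behavior parameters\n")
  cat(sprintf("  activity fraction: %s (circadian amplitude %.2f, peak ZT%g)\n",
              format(x$activity_fraction), x$circadian_amplitude,
              x$circadian_peak_zt))
  cat(sprintf("  startle: mean %.2f mm (sd %.2f), response prob %.3f, habituation decrement %.2f\n",
              x$startle_distance_mean, x$startle_distance_sd,
              x$startle_response_prob, x$habituation_decrement))
  cat(sprintf("  pigment gray: %.2f +/- %.2f (8-bit)\n",
              x$pigment_gray_mean, x$pigment_gray_sd))
  invisible(x)
}

#' Calibrated parameter presets for the study groups
#'
#' Returns [larva_params()] calibrated to the group-level endpoints of a
#' glucocorticoid-receptor (gr) mutant phenotyping study: wildtype larvae
#' spend ~9.5% of frames in motion versus ~7.0% for gr mutants; mutants
#' respond to taps on ~62.1% of trials (wildtype 43.1%) and travel 2.3 mm
#' versus 1.5 mm in the post-tap second; VBA+ (light) larvae average 82.91
#' gray levels dorsally versus 61.45 for VBA- (dark, mutant) larvae.
#' Fluoxetine-treated mutants are calibrated to the treated-group activity
#' level (15.4%).
#'
#' @param group One of `"wildtype"`, `"gr_mutant"`, `"gr_mutant_fluoxetine"`,
#'   `"wildtype_fluoxetine"`.
#' @return A `larva_params` object.
#' @examples
#' preset_params("gr_mutant")$activity_fraction
#' @export
preset_params <- function(group = c("wildtype", "gr_mutant",
                                    "gr_mutant_fluoxetine",
                                    "wildtype_fluoxetine")) {
  group <- match.arg(group)
  switch(group,
    wildtype = larva_params(
      activity_fraction = 0.095,
      startle_distance_mean = 1.5, startle_distance_sd = 2.2,
      startle_response_prob = 0.431,
      pigment_gray_mean = 82.91, pigment_gray_sd = 13.31),
    gr_mutant = larva_params(
      activity_fraction = 0.070,
      startle_distance_mean = 2.3, startle_distance_sd = 2.5,
      startle_response_prob = 0.621,
      pigment_gray_mean = 61.45, pigment_gray_sd = 10.04),
    gr_mutant_fluoxetine = larva_params(
      activity_fraction = 0.154,
      startle_distance_mean = 1.5, startle_distance_sd = 2.2,
      startle_response_prob = 0.431,
      pigment_gray_mean = 61.45, pigment_gray_sd = 10.04),
    wildtype_fluoxetine = larva_params(
      activity_fraction = 0.095,
      startle_distance_mean = 1.5, startle_distance_sd = 2.2,
      startle_response_prob = 0.431,
      pigment_gray_mean = 82.91, pigment_gray_sd = 13.31)
  )
}

#' Assign wells of a plate to experimental groups
#'
#' Maps each well of a plate layout to exactly one group label with its
#' behavioral parameters, encoding e.g. a 2x2 genotype-by-treatment design.
#'
#' @param layout A [plate_layout()].
#' @param groups Named list mapping group label to a [larva_params()] object.
#' @param wells Optional named list mapping group label to a character vector
#'   of well ids; by default wells are dealt to groups in plate order, as
#'   evenly as possible.
#' @return A data frame of class `group_assignment` with columns `well_id`
#'   and `group_label`, and the parameter list in attribute `params`.
#' @examples
#' lay <- plate_layout()
#' ga <- group_assignment(lay, list(wt = preset_params("wildtype"),
#'                                  mut = preset_params("gr_mutant")))
#' table(ga$group_label)
#' @export
group_assignment <- function(layout, groups, wells = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  if (length(groups) == 0) stop("at least one group required", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list", call. = FALSE)
  for (g in groups) validate_larva_params(g)
  ids <- layout$well_id
  if (is.null(wells)) {
    # contiguous blocks in plate order, as even as the well count allows
    n_per <- diff(round(seq(0, length(ids), length.out = length(groups) + 1)))
    lab <- rep(names(groups), times = n_per)
  } else {
    if (!setequal(names(wells), names(groups)))
      stop("wells must name the same groups", call. = FALSE)
    all_w <- unlist(wells, use.names = FALSE)
    if (anyDuplicated(all_w))
      stop("a well is assigned to more than one group", call. = FALSE)
    if (!all(all_w %in% ids))
      stop("unknown well id in assignment", call. = FALSE)
    lab <- rep(NA_character_, length(ids))
    for (g in names(wells)) lab[match(wells[[g]], ids)] <- g
    keep <- !is.na(lab)
    ids <- ids[keep]; lab <- lab[keep]
  }
  out <- data.frame(well_id = ids, group_label = lab,
                    stringsAsFactors = FALSE)
  structure(out, params = groups, class = c("group_assignment", "data.frame"))
}
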