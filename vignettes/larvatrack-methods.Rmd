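---
title: "Models and methods behind larvatrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind larvatrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatrack)
```

`larvatrack` reconstructs a complete behavioral-phenotyping chain for
larval zebrafish in multiwell plates: synthetic ground truth, video
rendering, centroid tracking, behavioral endpoints, pigmentation-based
genotype sorting, and the statistical layer. This vignette explains the
models behind each stage, the tunable parameters and their defaults, the
numerical choices, and what the simulation-based validation does and does
not establish about real data.

## The locomotion model

The literature on larval swimming agrees on one robust feature: larvae move
in discrete *swim bouts* separated by rest, rather than continuously. The
generator therefore models spontaneous locomotion as a Poisson process of
bouts. Each bout displaces the animal by a shifted-exponential distance
(`bout_min_mm` + Exp, default floor 0.4 mm, mean `bout_displacement_mean`
= 1 mm) in a uniformly random direction, with billiard reflection at the
well wall so path length is preserved. Positions are sampled at the
acquisition rate (0.5 Hz for the spontaneous assay, i.e. one frame per
2 s).

The key calibration contract is between the generator and the
`percent_time_in_motion` metric. A frame interval counts as "moving" when
the centroid displaces by more than the movement threshold (default
0.3 mm). Because every bout moves the larva at least `bout_min_mm` >
threshold, the probability that an interval is flagged equals the
probability that it contains at least one bout, so the per-interval bout
rate can be solved exactly from the target `activity_fraction`:
λ(t)·Δt = −log(1 − f(t)). Group activity levels (e.g. 7.0% for GR mutants,
9.5% for wildtype in `preset_params()`) are therefore recovered by the
measurement chain up to two small, understood biases: two bouts in one
interval can partially cancel vectorially (≈1% relative undercount at
these activity levels), and wall reflections shorten the straight-line
displacement slightly. Both are visible in the calibration checks (about
6.85% and 9.3% recovered for the 7.0/9.5 targets) and are well inside the
sampling error of a 48-larva experiment.

Two geometric choices matter for tracking realism. The larva's *centroid*
is confined to the well radius minus a body margin (`wall_margin_mm`,
default 0.35 mm): a physical animal's center of mass cannot reach the
glass. Correspondingly, the tracker searches a slightly dilated ROI
(`search_margin_mm`, default 0.6 mm, capped to keep wells disjoint) so the
image of a larva resting against the wall is not truncated by the ROI
boundary — without these, edge positions show a systematic inward bias.

## The circadian drive

Hourly activity is modulated by a 24 h sinusoid with relative amplitude
`circadian_amplitude` (default 0.5). Two refinements were needed to match
the qualitative structure of real recordings:

* **Phase convention.** Activity profiles are reported in hourly ZT bins.
  A sinusoid peaking exactly at ZT 13.0 would make the bins ZT 12 and
  ZT 13 identical in expectation (they flank the peak symmetrically), so
  `circadian_peak_zt` is defined as the *maximal hourly bin*, and the
  underlying sinusoid peaks at its center (`circadian_peak_zt + 0.5` h).
* **Light-phase masking.** Larvae entrained to a 14/10 light/dark cycle
  are more active during the subjective light phase, yet their activity
  peaks late in it (ZT 13, just before subjective lights-off). A pure
  sinusoid peaking at ZT 13 cannot produce a higher light-phase mean: over
  the 14 h light window its positive and negative lobes cancel almost
  exactly. Real profiles are asymmetric — activity ramps up through the
  light phase and collapses quickly after dark onset. The generator
  therefore multiplies the sinusoid by a two-level mask: `1 +
  light_phase_boost` during ZT 0–14 and correspondingly suppressed
  (scaled by 14/10) during ZT 14–24, renormalized over the full cycle so
  the mean activity stays exactly at `activity_fraction`. The default
  boost of 0.2 yields a light/dark activity ratio around 1.5, a
  mid-range value for entrained larvae.

With these defaults the group-mean hourly profile has its maximum in the
ZT 13 bin and a clearly higher light-phase mean, both verified by
simulation tests.

## Startle swims and habituation

Each tap elicits, per larva, a Bernoulli responder draw
(`startle_response_prob`) and a swim distance. Responder distances decay
multiplicatively within a 5-trial block by `habituation_decrement`
(default 0.8 per trial, resetting each block); non-responders are still
half the time and otherwise drift sub-criterion (0.05–0.9 mm). The 1 s,
100 Hz swim path is front-loaded: after an onset latency of 20–120 ms the
first ~1.2 mm is delivered in fast ~0.4 mm/10 ms steps (the C-bend and
early rapid swim), the remainder tapering off over the rest of the second.
This makes the responder criterion (>1 mm within 500 ms) and the
latency rule (first 10-ms step above 0.3 mm) both well defined on the
rendered kinematics.

Because the published group distances are means over the *analyzed*
trials — i.e. after excluding larvae that failed to respond on the first
trial of the first block — `startle_distance_mean` is defined on exactly
that quantity. The trial-1 responder mean is solved in closed form from
the target, the response probability, the decrement and the non-responder
distribution, so the post-filter group mean matches the parameter in
expectation. Responder distances are drawn as `1.4 mm + Gamma` with the
exact required mean (the 1.4 mm floor guarantees the criterion is
attainable) and a spread set by `startle_distance_sd` scaled by the
within-block decay.

One bias is accepted deliberately: group response *rates* are averaged
over all 25 analyzed trials, and trial 1 is 100% by construction of the
inclusion filter (as it is in the original analysis). With the per-trial
probability set directly to the published grand-mean rate, the recovered
grand mean is therefore higher by `(100 − rate)/25` — about 1.5–2.5
percentage points — which stays well inside the binomial sampling error of
a 24-larva session. The per-trial probability was kept as the primary,
interpretable parameter rather than back-solving it.

## Rendering and tracking

Frames are 8-bit, light background (value 200) with one dark blob per
occupied well: a flat-intensity body core (0.35 mm radius) with a Gaussian
skirt (σ = 0.1 mm), overall diameter ≈ 1 mm at the default 10 px/mm.
Each larva's body intensity is drawn once per session from its group's
pigmentation distribution; i.i.d. Gaussian pixel noise (default sd 2 gray
levels) is added to frames and reference alike, and values are rounded and
clamped — so the rendered stack quantizes exactly like real 8-bit video.

Tracking composes reference subtraction (clamped at zero), per-well disc
ROIs, and an intensity-weighted centroid over the largest 8-connected
component above threshold. The default threshold is an Otsu-style 1-D
two-means split of the ROI's difference intensities with a floor of 10
gray levels; the floor prevents the split from chasing noise in empty
wells. The largest-component rule rejects reflections and debris; pixel
centers are at half-integer coordinates with the origin at the top-left
image corner, and millimeter coordinates are centered per well. Round-trip
accuracy on rendered stacks is ~0.3 px RMS at noise sd 2 (bound: 0.5 px)
and ~0.03 mm RMS noiseless.

The body-core ROI used for pigmentation (`body_roi`) is geometric — all
pixels within 0.25 mm of the blob centroid — rather than an intensity
cut. Selecting pixels by intensity biases the measured gray level through
the noise (bright-noise pixels are preferentially excluded); selecting by
geometry recovers the rendered body value to well within one gray level.

## Statistics

The summary-statistic entry points (`group_summary`, `cohens_d`,
`pooled_t_test`, `welch_t_test`) exist so that published group values can
be regression-tested without raw data. Cohen's d uses the df-weighted
pooled sd when group sizes are given and the equal-n form
√((s₁² + s₂²)/2) otherwise; all p-values are two-sided; no
multiple-testing correction is applied anywhere (matching the analysis
conventions of the assay literature — flagged, not hidden).

`mixed_rm_anova` implements the split-plot decomposition on subject ×
level cell means (replicate observations per cell, e.g. trials within
blocks, are averaged first). The Greenhouse–Geisser ε̂ is computed from
the pooled (across between-groups) covariance matrix of the repeated
measures via the double-centered form ε̂ = (tr S̃)²/((k−1)·ΣS̃²),
clamped to its theoretical range [1/(k−1), 1]; at k = 2 it is exactly 1.
The correction multiplies both degrees of freedom of every within-subject
test. Partial η² is reported per effect against that effect's own error
term. The implementation is validated three ways: a brute-force
sum-of-squares oracle on a small fixed table (1e−8), agreement of all F
statistics with `stats::aov` with an `Error(subject/within)` stratum, and
a 1000-replicate null simulation (k = 5, 17 subjects per group) whose
GG-corrected type-I error must land in [0.03, 0.07] at α = 0.05 — it
comes out near 0.04–0.05, i.e. the familiar mild conservatism of the
correction under sphericity.

With unequal group sizes the cell-mean decomposition uses group-size
weighting (Type-I-like); the intended use is the balanced or
near-balanced designs of plate experiments.

## The pipeline

`run_pipeline()` chains simulate → (track) → metrics → stats → report.
Stages communicate only through files (CSV, TIFF, JSON) so each is
independently testable and replaceable; a manifest records the config
hash (MD5 of the canonical config, excluding the output path), the seed,
and the checksum of every output. There are deliberately no timestamps in
any output, so a rerun with identical config and seed is byte-identical.
Stage timing is logged to the console instead. The `track` stage operates
on rendered stacks and is intended for short validation segments;
rendering a full 24 h recording (43 200 frames per plate) is out of scope
for routine runs, and tracking accuracy is established separately by the
round-trip tests.

## Problem sizes used in the validation suite

The simulation-based checks run at the original experiments' scales where
that is what is being claimed: activity recovery uses 48 larvae per group over
24 h at 0.5 Hz, averaged over 50 seeded replicates; startle recovery uses
24 larvae per group (≈ 10–15 retained after first-trial filtering) over
50 replicates; pigmentation recovery renders 30 larvae per class per
replicate. Unit and property tests use deliberately small instances
(1–8 wells, minutes of recording) chosen for coverage, not for effect
estimation.

## What the synthetic data does and does not establish

The generator reproduces the *statistical structure* the analysis
assumes: bout-based motion with calibrated time-in-motion, a peaked and
light-dominant circadian profile, Bernoulli startle responding with
multiplicative within-block habituation, front-loaded startle kinematics,
and pigmentation classes with realistic separation. Passing the
round-trip and calibration tests therefore shows the *pipeline* is
correct and unbiased under these assumptions. It does not show that real
larvae satisfy the assumptions: the generator has no between-larva
individual variability beyond sampling noise (real group sds of activity
are several-fold larger than the simulated between-larva spread, so
simulated test statistics on group differences are much larger than
published ones), no posture or tail kinematics, one larva per well, no
slow drift or illumination artifacts in the rendered video, and
independence across trials apart from the deterministic habituation
trend. Conclusions about real recordings still require the usual checks
on the video itself (contrast, debris, dropped frames) and on the
plausibility of the fitted thresholds.

## Known limitations

* Between-larva variability is not modeled; calibration targets are group
  means, not group variances.
* The rm-ANOVA covers one between- and one within-subject factor; the
  2 × 2 genotype-by-treatment designs are analyzed per stratum (as
  separate analyses per treatment or genotype), not as a three-way model.
* Only the Greenhouse–Geisser correction is provided (no Huynh–Feldt).
* `classify_vba` assumes two pigmentation classes; heterozygote-dosage
  effects, if any, are folded into the class distributions.
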