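#' Mean dorsal grayscale intensity
#'
#' Average 8-bit intensity of the larva's dorsal surface over a region of
#' interest — the measurement behind visual-background-adaptation (VBA)
#' sorting, where mutant larvae fail to lighten and remain dark.
#'
#' @param image 8-bit grayscale matrix.
#' @param roi Logical matrix (same dimension) or index vector selecting the
#'   body pixels.
#' @return Mean intensity (numeric scalar).
#' @examples
#' img <- matrix(c(60, 60, 120, 120), 2, 2)
#' dorsal_grayscale(img, matrix(TRUE, 2, 2))
#' @export
dorsal_grayscale <- function(image, roi) {
  vals <- image[roi]
  if (length(vals) == 0) stop("empty ROI", call. = FALSE)
  if (any(vals < 0 | vals > 255))
    stop("image is not 8-bit (values outside 0-255)", call. = FALSE)
  mean(vals)
}

#' Body-core ROI from a difference image
#'
#' Selects the central dorsal surface of a larva for pigmentation
#' measurement: the body blob is located by its intensity-weighted centroid
#' in the difference image (via [locate_centroid()]), and all pixels within
#' `core_radius_mm` of that centroid are kept. Selecting by geometry rather
#' than by an intensity cut avoids biasing the measured gray level through
#' the pixel noise.
#'
#' @param diff_img Difference image ([subtract_reference()]).
#' @param px_per_mm Pixel calibration.
#' @param well_roi Logical matrix restricting the search to one well;
#'   defaults to the whole image.
#' @param core_radius_mm Radius of the measured disc around the body
#'   centroid (default 0.25 mm, inside the ~1 mm body blob).
#' @return Logical matrix marking body-core pixels (all `FALSE` when no
#'   larva is detected).
#' @export
body_roi <- function(diff_img, px_per_mm = 10, well_roi = NULL,
                     core_radius_mm = 0.25) {
  if (is.null(well_roi)) well_roi <- matrix(TRUE, nrow(diff_img),
                                            ncol(diff_img))
  ctr <- locate_centroid(diff_img, well_roi)
  out <- matrix(FALSE, nrow(diff_img), ncol(diff_img))
  if (is.na(ctr[1])) return(out)
  jr <- matrix(rep(seq_len(ncol(out)) - 0.5, each = nrow(out)), nrow(out))
  ir <- matrix(rep(seq_len(nrow(out)) - 0.5, times = ncol(out)), nrow(out))
  well_roi & (jr - ctr[1])^2 + (ir - ctr[2])^2 <=
    (core_radius_mm * px_per_mm)^2
}

#' Classify larvae as VBA+ / VBA- from pigmentation
#'
#' Splits dorsal grayscale measurements into a light (VBA+) and a dark
#' (VBA-, presumed homozygous mutant) class. The default `two_means` method
#' is an Otsu-style 1-D two-cluster split minimizing total within-class
#' variance — an automated surrogate for sorting by eye; `fixed_cut`
#' mimics a manual threshold.
#'
#' @param measurements Numeric vector of mean gray values (0-255), or a
#'   data frame with a `mean_gray` column.
#' @param method `"two_means"` or `"fixed_cut"`.
#' @param cut Gray threshold for `fixed_cut` (values below are VBA-).
#' @return Factor with levels `VBA-`, `VBA+` (VBA- is the darker class);
#'   the fitted threshold in attribute `threshold`. All-equal input yields
#'   a single class with a warning.
#' @examples
#' classify_vba(c(50, 51, 90, 91))
#' @export
classify_vba <- function(measurements, method = c("two_means", "fixed_cut"),
                         cut = NULL) {
  method <- match.arg(method)
  if (is.data.frame(measurements)) measurements <- measurements$mean_gray
  x <- as.numeric(measurements)
  if (method == "fixed_cut") {
    if (is.null(cut)) stop("fixed_cut requires a cut value", call. = FALSE)
    thr <- cut
  } else {
    if (length(x) < 2)
      stop("two_means needs at least 2 measurements", call. = FALSE)
    thr <- split_two_means(x)
    if (is.na(thr)) {
      warning("all measurements identical; single class")
      return(structure(factor(rep("VBA-", length(x)),
                              levels = c("VBA-", "VBA+")),
                       threshold = NA_real_))
    }
  }
  structure(factor(ifelse(x < thr, "VBA-", "VBA+"),
                   levels = c("VBA-", "VBA+")),
            threshold = thr)
}

#' Mendelian ratio goodness-of-fit test
#'
#' Pearson chi-square test of observed phenotype counts against expected
#' Mendelian proportions (no continuity correction), e.g. the 1:4 VBA-:VBA+
#' segregation expected among offspring of a heterozygous incross (1 of 4
#' larvae homozygous mutant).
#'
#' @param observed Non-negative integer vector of category counts.
#' @param expected_prop Expected proportions (summing to 1); default `c(1,
#'   3)/4` for the 1-in-4 recessive class.
#' @return An object of class `ratio_test` (and `stat_result`): `observed`,
#'   `expected`, `expected_prop`, `chi2`, `df`, `p`.
#' @examples
#' mendelian_ratio_test(c(47, 147))
#' @export
mendelian_ratio_test <- function(observed, expected_prop = c(1, 3) / 4) {
  if (length(observed) != length(expected_prop))
    stop("observed and expected lengths differ", call. = FALSE)
  if (any(observed < 0)) stop("counts must be >= 0", call. = FALSE)
  if (abs(sum(expected_prop) - 1) > 1e-8)
    stop("expected proportions must sum to 1", call. = FALSE)
  expected <- sum(observed) * expected_prop
  if (any(expected == 0))
    stop("zero expected count", call. = FALSE)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  structure(list(observed = observed, expected = expected,
                 expected_prop = expected_prop,
                 chi2 = chi2, df = df,
                 p = pchisq(chi2, df, lower.tail = FALSE)),
            class = c("ratio_test", "stat_result"))
}

#' @export
print.ratio_test <- function(x, digits = 2, ...) {
  cat(sprintf("Mendelian ratio test: observed (%s) vs expected (%s)\n",
              paste(x$observed, collapse = ", "),
              paste(format(x$expected_prop), collapse = " : ")))
  cat(sprintf("  chi2(%d, N = %d) = %.2f, p = %.2f\n",
              x$df, sum(x$observed), x$chi2, x$p))
  invisible(x)
}
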