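#' Group summary statistics
#'
#' Summary-statistic entry point for the statistics layer: published group
#' values ("mean +/- sd, n") can be fed straight into effect sizes and
#' t-tests without raw data.
#'
#' @param mean,sd Group mean and standard deviation (`sd >= 0`).
#' @param n Group size (>= 2), or `NA` when only an equal-n effect size is
#'   needed.
#' @param label Optional group label.
#' @return An object of class `group_summary`.
#' @examples
#' group_summary(9.5, 3.3, 48, "wildtype")
#' @export
group_summary <- function(mean, sd, n = NA_integer_, label = NA_character_) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (!is.na(n) && n < 2) stop("n must be >= 2", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = n, label = label),
            class = "group_summary")
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  if (is.numeric(x) && length(x) >= 2)
    return(group_summary(x[1], x[2], if (length(x) >= 3) x[3] else NA))
  stop("cannot interpret group summary", call. = FALSE)
}

#' Cohen's d from group summaries
#'
#' Pooled-standard-deviation standardized mean difference. With group sizes
#' the pooled sd weights by degrees of freedom; with equal or absent n it
#' reduces to `sqrt((s1^2 + s2^2) / 2)`.
#'
#' @param g1,g2 [group_summary()] objects (or numeric `c(mean, sd[, n])`).
#' @return Cohen's d (numeric scalar, signed as `g1 - g2`).
#' @examples
#' cohens_d(c(82.91, 13.31), c(61.45, 10.04))  # 1.82
#' @export
cohens_d <- function(g1, g2) {
  g1 <- as_group_summary(g1); g2 <- as_group_summary(g2)
  if (g1$sd == 0 && g2$sd == 0)
    stop("pooled sd is zero; d undefined", call. = FALSE)
  sp <- if (!is.na(g1$n) && !is.na(g2$n) && g1$n != g2$n) {
    sqrt(((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / (g1$n + g2$n - 2))
  } else {
    sqrt((g1$sd^2 + g2$sd^2) / 2)
  }
  (g1$mean - g2$mean) / sp
}

.stat_result <- function(name, value, df1, df2 = NA_real_, p = NA_real_,
                         effect_size = NA_real_, effect_name = NA_character_,
                         method = NULL) {
  structure(list(statistic_name = name, value = value, df1 = df1, df2 = df2,
                 p = p, effect_size = effect_size,
                 effect_name = effect_name, method = method),
            class = "stat_result")
}

#' Two-sample t-tests from group summaries
#'
#' `pooled_t_test` is the Student t-test with pooled variance
#' (df = n1 + n2 - 2); `welch_t_test` uses per-group variances with
#' Welch-Satterthwaite (fractional) degrees of freedom. Both are two-sided
#' and report Cohen's d alongside, as is conventional in this literature.
#'
#' @param g1,g2 [group_summary()] objects (or numeric `c(mean, sd, n)`);
#'   `n` required.
#' @return A `stat_result`: `value` (t), `df1`, `p`, `effect_size` (d).
#' @examples
#' pooled_t_test(c(62.1, 17.7, 25), c(43.1, 19.0, 25))  # t(48) = 3.66
#' welch_t_test(c(15.4, 4.9, 16), c(3.96, 2.2, 16))     # t(20.8) = 8.5
#' @export
pooled_t_test <- function(g1, g2) {
  g1 <- as_group_summary(g1); g2 <- as_group_summary(g2)
  if (is.na(g1$n) || is.na(g2$n))
    stop("group sizes required", call. = FALSE)
  df <- g1$n + g2$n - 2
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
  t <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  .stat_result("t", t, df, p = 2 * pt(-abs(t), df),
               effect_size = cohens_d(g1, g2), effect_name = "d",
               method = "pooled two-sample t-test")
}

#' @rdname pooled_t_test
#' @export
welch_t_test <- function(g1, g2) {
  g1 <- as_group_summary(g1); g2 <- as_group_summary(g2)
  if (is.na(g1$n) || is.na(g2$n))
    stop("group sizes required", call. = FALSE)
  if (g1$sd <= 0 || g2$sd <= 0)
    stop("Welch t requires positive sds", call. = FALSE)
  v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
  t <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  .stat_result("t", t, df, p = 2 * pt(-abs(t), df),
               effect_size = cohens_d(g1, g2), effect_name = "d",
               method = "Welch two-sample t-test")
}

format_p <- function(p) {
  if (is.na(p)) return("p = NA")
  if (p < 0.001) "p < 0.001" else sprintf("p = %.3f", p)
}

#' Round a statistic for reporting
#'
#' Formats a `stat_result` the way results sections print them: degrees of
#' freedom rounded to the nearest whole number (exact values retained in
#' the object), statistics to 2 decimals, effect sizes to 2 decimals.
#'
#' @param result A `stat_result`.
#' @return Character scalar, e.g. `"t(21) = 8.52, p < 0.001, d = 3.01"`.
#' @examples
#' report_round(welch_t_test(c(15.4, 4.9, 16), c(3.96, 2.2, 16)))
#' @export
report_round <- function(result) {
  stopifnot(inherits(result, "stat_result"))
  dfs <- if (is.na(result$df2)) sprintf("%d", round(result$df1)) else
    sprintf("%d, %d", round(result$df1), round(result$df2))
  out <- sprintf("%s(%s) = %.2f, %s", result$statistic_name, dfs,
                 result$value, format_p(result$p))
  if (!is.na(result$effect_size))
    out <- sprintf("%s, %s = %.2f", out, result$effect_name,
                   result$effect_size)
  out
}

#' @export
print.stat_result <- function(x, ...) {
  if (!is.null(x$method)) cat(x$method, "\n")
  cat("  ", report_round(x), "\n", sep = "")
  if (!is.na(x$df1) && x$df1 != round(x$df1))
    cat(sprintf("  (exact df: %s)\n",
                paste(signif(c(x$df1, x$df2)[!is.na(c(x$df1, x$df2))], 4),
                      collapse = ", ")))
  invisible(x)
}
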