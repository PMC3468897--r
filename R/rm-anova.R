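#' Mixed repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Split-plot (one between-subjects factor, one within-subjects factor)
#' analysis of variance as used for trial- and block-structured behavioral
#' data: the within main effect, the between main effect and their
#' interaction, each with partial eta squared. Sphericity of the repeated
#' measures is guarded by the Greenhouse-Geisser correction: an epsilon
#' estimated from the pooled (across groups) covariance matrix of the
#' within-subject measures multiplies the degrees of freedom of all
#' within-subject tests.
#'
#' Subjects with missing cells are dropped with a warning (complete-case
#' analysis). Group sizes may differ; cell sizes within a subject may not.
#'
#' @param data Long-format data frame.
#' @param subject,group,within,value Names of the columns holding the
#'   subject id, between-group label, within-subject level and response.
#' @param gg_correct Apply the Greenhouse-Geisser df correction to
#'   within-subject effects (default `TRUE`).
#' @return An object of class `rm_anova`: `table` (one row per effect with
#'   `SS`, `df1`, `df2`, `df1_gg`, `df2_gg`, `F`, `p`, `eta_p2`),
#'   `epsilon` (the GG estimate), `k` (within levels), `n_subjects`, and
#'   `gg_correct`.
#' @examples
#' d <- expand.grid(subject = 1:6, trial = 1:3)
#' d$group <- ifelse(d$subject <= 3, "a", "b")
#' d$value <- rnorm(nrow(d)) + d$trial * 0.5
#' fit <- mixed_rm_anova(d, subject = "subject", group = "group",
#'                       within = "trial", value = "value")
#' fit$table
#' @export
mixed_rm_anova <- function(data, subject = "subject", group = "group",
                           within = "within", value = "value",
                           gg_correct = TRUE) {
  d <- data.frame(subject = factor(data[[subject]]),
                  group = factor(data[[group]]),
                  within = factor(data[[within]]),
                  value = as.numeric(data[[value]]))
  k <- nlevels(d$within)
  if (k < 2) stop("need >= 2 within-subject levels", call. = FALSE)
  # complete cases: every subject needs every within level; replicate
  # observations per subject x level (e.g. trials within blocks) are
  # averaged to cell means
  tab <- table(d$subject, d$within)
  complete <- rownames(tab)[apply(tab >= 1, 1, all)]
  if (length(complete) < nlevels(d$subject)) {
    warning(sprintf("%d subject(s) with missing cells excluded",
                    nlevels(d$subject) - length(complete)))
    d <- d[d$subject %in% complete, ]
    d$subject <- droplevels(d$subject)
    d$group <- droplevels(d$group)
  }
  if (any(tab[complete, ] > 1)) {
    d <- stats::aggregate(value ~ subject + group + within, data = d,
                          FUN = mean)
  }
  # wide response matrix, one row per subject
  d <- d[order(d$subject, d$within), ]
  Y <- matrix(d$value, ncol = k, byrow = TRUE)
  subj <- d$subject[seq(1, nrow(d), by = k)]
  g <- d$group[seq(1, nrow(d), by = k)]
  N <- nrow(Y)
  n_g <- table(g)
  if (any(n_g < 2))
    stop("need >= 2 subjects per group", call. = FALSE)
  G <- length(n_g)

  M <- mean(Y)
  ms <- rowMeans(Y)                       # subject means
  mt <- colMeans(Y)                       # within-level means
  mg <- tapply(ms, g, mean)               # group means
  mgt <- apply(Y, 2, function(col) tapply(col, g, mean))  # G x k cell means
  if (G == 1) mgt <- matrix(mgt, nrow = 1)

  n_g <- as.numeric(n_g)
  ss_between_tot <- k * sum((ms - M)^2)
  ss_group <- k * sum(n_g * (mg - M)^2)
  ss_subj <- ss_between_tot - ss_group
  ss_within_tot <- sum((Y - ms)^2)
  ss_time <- N * sum((mt - M)^2)
  ss_int <- sum(n_g * (mgt - outer(as.numeric(mg), rep(1, k)) -
                         outer(rep(1, G), mt) + M)^2)
  ss_err_w <- ss_within_tot - ss_time - ss_int

  df_group <- G - 1; df_subj <- N - G
  df_time <- k - 1; df_int <- (G - 1) * (k - 1); df_err_w <- (N - G) * (k - 1)

  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  S <- Reduce(`+`, lapply(levels(g), function(gl) {
    Yg <- Y[g == gl, , drop = FALSE]
    (nrow(Yg) - 1) * stats::cov(Yg)
  })) / (N - G)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  denom <- (k - 1) * sum(Sc^2)
  eps <- if (denom <= 0) 1 else sum(diag(Sc))^2 / denom
  eps <- min(max(eps, 1 / (k - 1)), 1)

  mk_row <- function(effect, ss, df1, df2, ss_err, corr) {
    Fv <- (ss / df1) / (ss_err / df2)
    e <- if (corr && gg_correct) eps else 1
    data.frame(effect = effect, SS = ss, df1 = df1, df2 = df2,
               df1_gg = df1 * e, df2_gg = df2 * e, F = Fv,
               p = pf(Fv, df1 * e, df2 * e, lower.tail = FALSE),
               eta_p2 = ss / (ss + ss_err), stringsAsFactors = FALSE)
  }
  tab_out <- rbind(
    mk_row("within", ss_time, df_time, df_err_w, ss_err_w, TRUE),
    mk_row("between", ss_group, df_group, df_subj, ss_subj, FALSE),
    mk_row("within:between", ss_int, df_int, df_err_w, ss_err_w, TRUE))

  structure(list(table = tab_out, epsilon = eps, k = k, n_subjects = N,
                 n_groups = G, gg_correct = gg_correct,
                 ss = list(within = ss_time, between = ss_group,
                           interaction = ss_int, error_within = ss_err_w,
                           error_between = ss_subj,
                           total = ss_group + ss_subj + ss_time + ss_int +
                             ss_err_w)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Mixed repeated-measures ANOVA (%d subjects, %d group(s), %d within levels)\n",
              x$n_subjects, x$n_groups, x$k))
  cat(sprintf("Greenhouse-Geisser epsilon = %.3f%s\n", x$epsilon,
              if (x$gg_correct) " (applied to within-subject dfs)" else
                " (not applied)"))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("  %-15s [F(%d, %d) = %.2f, %s, eta_p2 = %.2f]\n",
                r$effect, round(r$df1_gg), round(r$df2_gg), r$F,
                format_p(r$p), r$eta_p2))
  }
  invisible(x)
}

#' @export
summary.rm_anova <- function(object, ...) {
  object$table
}

#' Extract an effect from a fitted rm-ANOVA as a `stat_result`
#'
#' @param fit An [mixed_rm_anova()] fit.
#' @param effect One of `"within"`, `"between"`, `"within:between"`.
#' @return A `stat_result` (F statistic, GG-corrected dfs and p, partial
#'   eta squared as effect size).
#' @export
anova_effect <- function(fit, effect = c("within", "between",
                                         "within:between")) {
  effect <- match.arg(effect)
  r <- fit$table[fit$table$effect == effect, ]
  .stat_result("F", r$F, r$df1_gg, r$df2_gg, p = r$p,
               effect_size = r$eta_p2, effect_name = "eta_p2",
               method = sprintf("rm-ANOVA %s effect", effect))
}
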