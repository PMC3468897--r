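test_that("Cohen's d reproduces published effect sizes from summaries", {
  expect_equal(round(cohens_d(c(82.91, 13.31), c(61.45, 10.04)), 2), 1.82)
  expect_equal(round(cohens_d(c(21.2, 18.7), c(3.95, 2.2)), 2), 1.30)
  expect_equal(round(cohens_d(c(15.4, 4.9), c(3.96, 2.2)), 2), 3.01)
  expect_equal(round(cohens_d(c(62.1, 17.7), c(43.1, 19.0)), 2), 1.03)
})

test_that("Cohen's d properties: antisymmetry, zero, degenerate input", {
  expect_equal(cohens_d(c(5, 2), c(3, 1)), -cohens_d(c(3, 1), c(5, 2)))
  expect_equal(cohens_d(c(4, 2), c(4, 2)), 0)
  expect_error(cohens_d(c(1, 0), c(2, 0)), "pooled sd")
  # unequal n uses df-weighted pooling
  d <- cohens_d(group_summary(10, 2, 5), group_summary(8, 4, 50))
  sp <- sqrt((4 * 4 + 49 * 16) / 53)
  expect_equal(d, 2 / sp)
})

test_that("pooled and Welch t reproduce published statistics", {
  t1 <- pooled_t_test(c(62.1, 17.7, 25), c(43.1, 19.0, 25))
  expect_equal(round(t1$value, 2), 3.66)
  expect_equal(t1$df1, 48)
  t2 <- pooled_t_test(c(21.2, 18.7, 16), c(3.95, 2.2, 16))
  expect_equal(round(t2$value, 1), 3.7)
  expect_equal(t2$df1, 30)
  t3 <- welch_t_test(c(15.4, 4.9, 16), c(3.96, 2.2, 16))
  expect_equal(round(t3$value, 1), 8.5)
  expect_lt(abs(t3$df1 - 20.8), 0.2)
})

test_that("summary-based tests agree with stats::t.test on raw data", {
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(12, 5, 2); y <- rnorm(17, 3, 4)
    gx <- group_summary(mean(x), sd(x), length(x))
    gy <- group_summary(mean(y), sd(y), length(y))
    tp <- pooled_t_test(gx, gy)
    ref_p <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(tp$value, unname(ref_p$statistic), tolerance = 1e-10)
    expect_equal(tp$p, ref_p$p.value, tolerance = 1e-10)
    tw <- welch_t_test(gx, gy)
    ref_w <- stats::t.test(x, y)
    expect_equal(tw$value, unname(ref_w$statistic), tolerance = 1e-10)
    expect_equal(tw$df1, unname(ref_w$parameter), tolerance = 1e-10)
    expect_equal(tw$p, ref_w$p.value, tolerance = 1e-10)
  }
})

test_that("Welch equals pooled t under equal variances and equal n", {
  tp <- pooled_t_test(c(10, 3, 20), c(8, 3, 20))
  tw <- welch_t_test(c(10, 3, 20), c(8, 3, 20))
  expect_equal(tp$value, tw$value, tolerance = 1e-12)
  expect_equal(tp$df1, tw$df1, tolerance = 1e-12)
  expect_error(pooled_t_test(c(1, 2), c(3, 4)), "sizes")
  expect_error(pooled_t_test(c(1, 0, 5), c(1, 0, 5)), "variance")
})

test_that("mixed rm-ANOVA matches a brute-force cell-means oracle", {
  # 4 subjects x 3 within levels, 2 groups: SS computed longhand
  Y <- matrix(c(3, 5, 4,
                4, 6, 6,
                7, 9, 8,
                8, 11, 9), nrow = 4, byrow = TRUE)
  d <- data.frame(subject = rep(1:4, each = 3),
                  group = rep(c("a", "a", "b", "b"), each = 3),
                  within = rep(1:3, 4),
                  value = as.vector(t(Y)))
  fit <- mixed_rm_anova(d)
  M <- mean(Y)
  ms <- rowMeans(Y); mt <- colMeans(Y)
  mg <- c(a = mean(Y[1:2, ]), b = mean(Y[3:4, ]))
  ss_group <- 0; ss_subj <- 0; ss_time <- 0; ss_int <- 0; ss_err <- 0
  grp <- c("a", "a", "b", "b")
  for (i in 1:4) {
    ss_subj <- ss_subj + 3 * (ms[i] - mg[grp[i]])^2
    for (t in 1:3) {
      mgt <- mean(Y[grp == grp[i], t])
      ss_err <- ss_err + (Y[i, t] - mgt - ms[i] + mg[grp[i]])^2
    }
  }
  for (g in c("a", "b")) {
    ss_group <- ss_group + 2 * 3 * (mg[g] - M)^2
    for (t in 1:3)
      ss_int <- ss_int + 2 * (mean(Y[grp == g, t]) - mg[g] - mt[t] + M)^2
  }
  ss_time <- 4 * sum((mt - M)^2)
  expect_equal(fit$ss$between, unname(ss_group), tolerance = 1e-8)
  expect_equal(fit$ss$error_between, unname(ss_subj), tolerance = 1e-8)
  expect_equal(fit$ss$within, unname(ss_time), tolerance = 1e-8)
  expect_equal(fit$ss$interaction, unname(ss_int), tolerance = 1e-8)
  expect_equal(fit$ss$error_within, unname(ss_err), tolerance = 1e-8)
  # conservation: SS components add to total variation around the grand mean
  expect_equal(fit$ss$total, sum((Y - M)^2), tolerance = 1e-8)
})

test_that("rm-ANOVA F statistics agree with stats::aov", {
  set.seed(123)
  d <- expand.grid(subject = factor(1:12), within = factor(1:4))
  d$group <- factor(ifelse(as.integer(d$subject) <= 6, "a", "b"))
  d$value <- rnorm(nrow(d)) + as.integer(d$within) * 0.4 +
    (d$group == "a") * 0.8
  fit <- mixed_rm_anova(d)
  ref <- summary(stats::aov(value ~ group * within +
                              Error(subject / within), data = d))
  between <- ref[["Error: subject"]][[1]]
  within <- ref[["Error: subject:within"]][[1]]
  expect_equal(fit$table$F[fit$table$effect == "between"],
               between["group", "F value"], tolerance = 1e-10)
  expect_equal(fit$table$F[fit$table$effect == "within"],
               within["within", "F value"], tolerance = 1e-10)
  expect_equal(fit$table$F[fit$table$effect == "within:between"],
               within["group:within", "F value"], tolerance = 1e-10)
})

test_that("Greenhouse-Geisser epsilon is bounded and exact at k = 2", {
  set.seed(5)
  d2 <- expand.grid(subject = factor(1:10), within = factor(1:2))
  d2$group <- factor(rep(c("a", "b"), 5))[d2$subject]
  d2$value <- rnorm(20)
  expect_equal(mixed_rm_anova(d2)$epsilon, 1)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    n <- sample(6:12, 1) * 2
    d <- expand.grid(subject = factor(seq_len(n)), within = factor(1:k))
    d$group <- factor(rep(c("a", "b"), n / 2))[d$subject]
    d$value <- rnorm(n * k) * rep(runif(k, 0.5, 3), each = n)
    fit <- mixed_rm_anova(d)
    expect_gte(fit$epsilon, 1 / (k - 1))
    expect_lte(fit$epsilon, 1)
    expect_true(all(fit$table$eta_p2 >= 0 & fit$table$eta_p2 <= 1))
  }
  # compound-symmetric covariance: epsilon = 1
  set.seed(6)
  n <- 40; k <- 4
  common <- rnorm(n, sd = 2)
  Y <- matrix(rnorm(n * k), n, k) + common
  d <- data.frame(subject = rep(seq_len(n), times = k),
                  group = rep(c("a", "b"), n / 2)[rep(seq_len(n), k)],
                  within = rep(seq_len(k), each = n), value = as.vector(Y))
  expect_gt(mixed_rm_anova(d)$epsilon, 0.85)
})

test_that("rm-ANOVA input contracts: missing cells, tiny groups", {
  d <- expand.grid(subject = factor(1:6), within = factor(1:3))
  d$group <- factor(ifelse(as.integer(d$subject) <= 3, "a", "b"))
  d$value <- rnorm(18)
  expect_warning(fit <- mixed_rm_anova(d[-1, ]), "excluded")
  expect_equal(fit$n_subjects, 5)
  expect_error(mixed_rm_anova(d[d$within == 1, ]), "within")
  d2 <- d[d$subject %in% c(1, 4), ]
  expect_error(suppressWarnings(mixed_rm_anova(d2)), "2 subjects")
})

test_that("report rounding displays whole dfs and 2-dp statistics", {
  tw <- welch_t_test(c(15.4, 4.9, 16), c(3.96, 2.2, 16))
  txt <- report_round(tw)
  expect_match(txt, "^t\\(21\\) = 8\\.52, p < 0\\.001, d = 3\\.01$")
  # exact fractional df retained in the object
  expect_false(tw$df1 == round(tw$df1))
  # GG-corrected dfs are multiplied by epsilon, then rounded for display
  sr <- larvatrack:::.stat_result("F", 5.1234, df1 = 4 * 0.437,
                                  df2 = 64 * 0.437, p = 0.01,
                                  effect_size = 0.16,
                                  effect_name = "eta_p2")
  expect_match(report_round(sr), "^F\\(2, 28\\) = 5\\.12")
})
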