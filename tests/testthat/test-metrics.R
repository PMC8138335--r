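test_that("bias is the percentage difference of means", {
  expect_equal(bias_percent(2.98, 2.98), 0)
  expect_equal(bias_percent(2.99, 2.98), 100 * 0.01 / 2.98)
  expect_equal(bias_percent(6.96, 4.30), 100 * 2.66 / 4.30)  # ~61.86
  expect_error(bias_percent(1, 0), "positive")
})

test_that("COV uses the sample SD over the mean", {
  expect_equal(cov_percent(c(1, 2, 3)), 50)
  expect_equal(cov_percent(rep(4, 5)), 0)
  expect_equal(cov_percent(10 * c(1, 2, 3)), 50)  # scale invariance
  expect_error(cov_percent(c(-2, 0, 2)), "positive")
  expect_error(cov_percent(3), "two values")
})

test_that("effect size uses the combined-sample SD and matches raw data", {
  expect_equal(cohens_d(c(2, 2), c(0, 0)), 2 / sqrt(4 / 3))
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(sample(5:40, 1), 3, 1)
    y <- rnorm(sample(5:40, 1), 1.5, 0.8)
    # moment reconstruction is algebraically identical to the raw pooled sample
    expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sd(c(x, y)),
                 tolerance = 1e-12)
    expect_equal(cov_percent_moments(mean(x), sd(x), length(x),
                                     mean(y), sd(y), length(y)),
                 cov_percent(c(x, y)), tolerance = 1e-12)
  }
})

test_that("pooled two-sample t and the Bonferroni cap behave as printed", {
  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-9)  # -3.674
  expect_equal(tt$p_adjusted, min(1, 2 * tt$p))
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_adjusted, 1)
  welch <- two_sample_t(c(1, 2, 3), c(4, 6, 8), var_equal = FALSE)
  expect_false(isTRUE(all.equal(welch$df, 4)))
})

test_that("AUC equals brute-force pair counting", {
  expect_equal(roc_auc(c(3, 5), c(1, 4)), 0.75)
  expect_equal(roc_auc(c(10, 11), c(1, 2)), 1)
  expect_equal(roc_auc(c(2, 2), c(2, 2)), 0.5)
  set.seed(7)
  for (i in 1:50) {
    x <- round(rnorm(sample(2:50, 1), 1, 1), 1)  # rounding forces ties
    y <- round(rnorm(sample(2:50, 1), 0, 1), 1)
    expect_equal(roc_auc(x, y), brute_force_auc(x, y))
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rnorm(30, 3); y <- rnorm(40, 1)
  a <- roc_auc(x, y)
  expect_equal(roc_auc(exp(x), exp(y)), a)
  expect_equal(roc_auc(2 * x + 5, 2 * y + 5), a)
})

test_that("AUC cross-checks against an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  x <- rnorm(24, 4.15, 0.88); y <- rnorm(33, 1.51, 0.61)
  r <- pROC::roc(response = rep(c(1, 0), c(24, 33)), predictor = c(x, y),
                 quiet = TRUE, direction = "<")
  expect_equal(roc_auc(x, y), as.numeric(pROC::auc(r)), tolerance = 1e-12)
})

test_that("absolute variability is symmetric and scale-free", {
  expect_equal(abs_var(2, 2), 0)
  expect_equal(abs_var(2.0, 1.8), 100 * 0.2 / 1.9)
  expect_equal(abs_var(1.8, 2.0), abs_var(2.0, 1.8))
  expect_equal(abs_var(180, 200), abs_var(1.8, 2.0))
  expect_error(abs_var(1, -1), "non-zero")
})

test_that("one-way ICC reproduces its ANOVA definition and edge values", {
  expect_equal(icc_oneway(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(icc_oneway(c(0, 2), c(2, 0)), -1)
  expect_error(icc_oneway(c(1, 1), c(1, 1)), "identical")
  set.seed(10)
  for (i in 1:50) {
    n <- sample(3:30, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, 2, 1), n, k) + rnorm(n, 0, 1)
    expect_equal(icc_oneway(m), anova_icc_oracle(m), tolerance = 1e-12)
  }
})

test_that("ICC cross-checks against aov mean squares", {
  set.seed(11)
  n <- 40
  subj <- factor(rep(seq_len(n), each = 2))
  y <- rnorm(n, 0, 1)[as.integer(subj)] + rnorm(2 * n, 0, 1)
  ms <- summary(aov(y ~ subj))[[1]]$`Mean Sq`
  expect_equal(icc_oneway(matrix(y, n, 2, byrow = TRUE)),
               (ms[1] - ms[2]) / (ms[1] + ms[2]), tolerance = 1e-12)
})

test_that("ICC estimates the variance-component ratio in simulation", {
  set.seed(12)
  n <- 500
  subj <- rnorm(n, 5, 1)
  m <- cbind(subj + rnorm(n), subj + rnorm(n))
  expect_lt(abs(icc_oneway(m) - 0.5), 0.1)
})

test_that("SEM follows sigma * sqrt(1 - ICC)", {
  vals <- c(1, 2, 3, 4)
  expect_equal(sem_measure(vals, 1), 0)
  expect_equal(sem_measure(vals, 0), sd(vals))
  expect_equal(sem_measure(c(0, 2, 2, 0), -1), sd(c(0, 2, 2, 0)) * sqrt(2))
  expect_error(sem_measure(vals, 1.2), "icc")
})

test_that("APC is the baseline-relative change per year", {
  expect_equal(apc(2.0, 1.6, 2), -10)
  expect_equal(apc(3, 3, 5), 0)
  expect_equal(apc(c(2, 4), c(1.6, 3.2), c(2, 2)), c(-10, -10))
  expect_error(apc(0, 1, 2), "positive")
  expect_error(apc(1, 2, 0), "positive")
})

test_that("paired t handles the printed cases and degeneracies", {
  pt <- paired_t(c(1, 2, 3), c(2, 2, 5))
  expect_equal(pt$t, sqrt(3), tolerance = 1e-9)  # mean diff 1, sd 1
  expect_equal(paired_t(c(1, 2), c(1, 2))$t, 0)
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "variance")
})

test_that("linear agreement recovers exact and null relations", {
  x <- c(1, 2, 3, 4, 5)
  fit <- suppressWarnings(linear_agreement(x, 2 * x + 1))  # perfect-fit note
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  y <- c(1, -1, 0, 1, -1)
  y <- y - sum(y * (x - mean(x))) / sum((x - mean(x))^2) * (x - mean(x))
  expect_lt(linear_agreement(x, y)$r_squared, 1e-20)
  expect_error(linear_agreement(rep(1, 5), x), "variance")
})
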