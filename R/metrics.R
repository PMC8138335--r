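#' Percentage bias of a simplified measure against the reference standard
#'
#' `100 * (mean_sbr - mean_bp) / mean_bp`: percentage difference between
#' the group-mean SBR and the group-mean SRTM BP_ND.
#'
#' @param mean_sbr group mean of the simplified outcome.
#' @param mean_bp group mean of the reference BP_ND, > 0.
#' @return bias in percent.
#' @export
bias_percent <- function(mean_sbr, mean_bp) {
  if (!is.finite(mean_bp) || mean_bp <= 0) stop("mean_bp must be positive")
  100 * (mean_sbr - mean_bp) / mean_bp
}

#' Coefficient of variation of a sample, in percent
#'
#' `100 * sd / mean` with the sample SD (denominator n - 1). For
#' between-subject variability of a binding measure this is computed over
#' the combined controls + patients sample.
#'
#' @param values numeric vector, n >= 2, positive mean.
#' @return COV in percent.
#' @export
cov_percent <- function(values) {
  if (length(values) < 2) stop("need at least two values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean must be positive")
  100 * stats::sd(values) / m
}

#' @rdname cov_percent
#' @param m1,s1,n1,m2,s2,n2 group means, SDs and sizes; the combined-sample
#'   mean and SD are reconstructed algebraically from the moments.
#' @export
cov_percent_moments <- function(m1, s1, n1, m2, s2, n2) {
  cs <- combined_moments(m1, s1, n1, m2, s2, n2)
  if (cs$mean <= 0) stop("combined mean must be positive")
  100 * cs$sd / cs$mean
}

# Mean and sample SD of the pooled two-group sample from group moments.
combined_moments <- function(m1, s1, n1, m2, s2, n2) {
  n <- n1 + n2
  m <- (n1 * m1 + n2 * m2) / n
  ss <- (n1 - 1) * s1^2 + (n2 - 1) * s2^2 + n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  list(mean = m, sd = sqrt(ss / (n - 1)), n = n)
}

#' Cohen's effect size with combined-sample standardiser
#'
#' `d = (mean_controls - mean_patients) / sd_combined`, where the
#' standardiser is the sample SD of the pooled two-group sample (not the
#' classical within-group pooled SD). This convention makes the effect
#' size and the combined-sample COV internally consistent.
#'
#' @param x,y raw values for the two groups (controls first).
#' @return effect size d.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  cohens_d_moments(mean(x), stats::sd(x), length(x),
                   mean(y), stats::sd(y), length(y))
}

#' @rdname cohens_d
#' @param m1,s1,n1,m2,s2,n2 group means, SDs and sizes (controls first).
#' @export
cohens_d_moments <- function(m1, s1, n1, m2, s2, n2) {
  cs <- combined_moments(m1, s1, n1, m2, s2, n2)
  if (cs$sd == 0) stop("zero combined SD")
  (m1 - m2) / cs$sd
}

#' Two-sample t test with Bonferroni adjustment
#'
#' Pooled-variance Student's t by default (Welch via `var_equal = FALSE`);
#' the p value is multiplied by `bonferroni_m` (two striatal VOIs) and
#' capped at 1.
#'
#' @param x,y raw group values.
#' @param var_equal pooled (`TRUE`, default) or Welch t test.
#' @param bonferroni_m number of comparisons, default 2.
#' @return list: `t`, `df`, `p`, `p_adjusted`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE, bonferroni_m = 2) {
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, p_adjusted = min(1, tt$p.value * bonferroni_m))
}

#' ROC area under the curve (Mann-Whitney form)
#'
#' `AUC = [#(control > patient) + 0.5 * #(control = patient)] / (n1 * n2)`,
#' the probability that a randomly chosen control exceeds a randomly chosen
#' patient; identical to the trapezoidal area under the full-threshold ROC
#' curve. Reported for the controls-higher discrimination direction
#' (controls have higher striatal binding).
#'
#' @param controls,patients raw group values, both non-empty.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(controls, patients) {
  if (!length(controls) || !length(patients)) stop("both groups must be non-empty")
  n1 <- length(controls); n2 <- length(patients)
  r <- rank(c(controls, patients), ties.method = "average")
  # rank-sum identity: sum of control ranks = U + n1(n1+1)/2
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Absolute test-retest variability, in percent
#'
#' `100 * |v2 - v1| / ((v1 + v2) / 2)`: the absolute difference between two
#' measurements over their mean. Vectorised over pairs.
#'
#' @param v1,v2 measurements at the first and second scan.
#' @return AbsVar in percent, per pair.
#' @export
abs_var <- function(v1, v2) {
  pm <- (v1 + v2) / 2
  if (any(pm == 0)) stop("pair mean must be non-zero")
  100 * abs(v2 - v1) / pm
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' From the one-way ANOVA decomposition over subjects:
#' `ICC = (MSB - MSW) / (MSB + (k - 1) * MSW)` with k measurements per
#' subject; range [-1/(k-1), 1].
#'
#' @param values n x k matrix (rows = subjects) or, with `v2` given, the
#'   first of two paired measurement vectors.
#' @param v2 optional second measurement vector (k = 2 shortcut).
#' @return ICC estimate.
#' @export
icc_oneway <- function(values, v2 = NULL) {
  m <- if (!is.null(v2)) cbind(values, v2) else as.matrix(values)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 subjects with >= 2 measurements each")
  grand <- mean(m)
  row_means <- rowMeans(m)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((m - row_means)^2) / (n * (k - 1))
  denom <- msb + (k - 1) * msw
  if (denom == 0) stop("all measurements identical; ICC undefined")
  (msb - msw) / denom
}

#' Standard error of measurement
#'
#' `SEM = sigma * sqrt(1 - ICC)`, with sigma the sample SD over all
#' measurements of all subjects pooled (both scans of each individual).
#'
#' @param values all measurements pooled (e.g. `c(v1, v2)`), or an n x k
#'   matrix.
#' @param icc the ICC of the same measurements, <= 1.
#' @return SEM in the units of the measurement.
#' @export
sem_measure <- function(values, icc) {
  if (!is.finite(icc) || icc > 1) stop("icc must be <= 1")
  stats::sd(as.numeric(values)) * sqrt(1 - icc)
}

#' Annual percentage change
#'
#' `APC = 100 * (v2 - v1) / v1 / interval_years`: the relative change from
#' baseline divided by the scan interval. Vectorised over subjects.
#'
#' @param v1,v2 baseline and follow-up values, `v1 > 0`.
#' @param interval_years inter-scan interval, > 0.
#' @return APC in percent per year, per subject.
#' @export
apc <- function(v1, v2, interval_years) {
  if (any(v1 <= 0)) stop("baseline values must be positive")
  if (any(interval_years <= 0)) stop("interval must be positive")
  100 * (v2 - v1) / v1 / interval_years
}

#' Paired t test with Bonferroni adjustment
#'
#' @param v1,v2 paired measurements (>= 2 pairs, non-degenerate differences).
#' @param bonferroni_m number of comparisons, default 2.
#' @return list: `t`, `df`, `p`, `p_adjusted`.
#' @export
paired_t <- function(v1, v2, bonferroni_m = 2) {
  d <- v2 - v1
  if (length(d) < 2) stop("need at least two pairs")
  if (all(d == 0)) {
    return(list(t = 0, df = length(d) - 1, p = 1, p_adjusted = 1))
  }
  if (stats::sd(d) == 0) stop("zero difference variance")
  tt <- stats::t.test(v2, v1, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, p_adjusted = min(1, tt$p.value * bonferroni_m))
}

#' Linear agreement between a simplified measure and BP_ND
#'
#' Ordinary least squares of `y` on `x` with the squared Pearson
#' correlation as r^2.
#'
#' @param x reference values (BP_ND).
#' @param y simplified outcome values (SBR).
#' @return list: `slope`, `intercept`, `r_squared`, `p` (slope test).
#' @export
linear_agreement <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) stop("need n >= 3 matched values")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p = unname(s$coefficients[2, 4]))
}
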