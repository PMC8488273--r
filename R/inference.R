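# Decision criteria: intercept comparisons, variance tests, classification.
#
# A significant amount-vs-score correlation admits two explanations:
#  * learning changed the protein during training, or
#  * the protein marks a pre-existing predisposition to learn readily.
# The two are separated by what they predict for variances: under a
# predisposition the protein contributes to the correlation, so the residual
# variance about the regression falls below the untrained-group variance
# while the total trained variance stays comparable; under learning the
# residual variance should be at least as large as the untrained baseline and
# the level extrapolated to the maximum score should differ from the
# untrained mean. The score-50 intercept vs the untrained mean detects
# training side-effects unrelated to learning.

#' Welch two-sample comparison of two estimates
#'
#' Compares two estimates with standard errors and degrees of freedom (e.g.
#' the regression intercept at a preference score vs the untrained-group
#' mean) by a Welch t statistic with Satterthwaite degrees of freedom:
#' `t = (A - B) / sqrt(seA^2 + seB^2)`,
#' `df = (seA^2 + seB^2)^2 / (seA^4/dfA + seB^4/dfB)`.
#'
#' @param est_a,se_a,df_a First estimate, its SE and df.
#' @param est_b,se_b,df_b Second estimate, its SE and df.
#' @param tail `"two"` (default) or `"one"` (one-sided in the observed
#'   direction).
#' @return An object of class `comparison_result`: list with
#'   `estimate_diff`, `t`, `df` (fractional), `p`, `tail`.
#' @export
welch_compare <- function(est_a, se_a, df_a, est_b, se_b, df_b,
                          tail = c("two", "one")) {
  tail <- match.arg(tail)
  for (nm in c("est_a", "se_a", "df_a", "est_b", "se_b", "df_b")) {
    assert_number(get(nm), nm)
  }
  if (se_a < 0 || se_b < 0) {
    stop_imprint("standard errors must be nonnegative", "invalid_argument")
  }
  if (se_a == 0 && se_b == 0) {
    stop_imprint("both standard errors are 0: comparison degenerates to exact equality",
                 "degenerate_comparison")
  }
  if (df_a <= 0 || df_b <= 0) {
    stop_imprint("degrees of freedom must be positive", "invalid_argument")
  }
  v <- se_a^2 + se_b^2
  tstat <- (est_a - est_b) / sqrt(v)
  df <- v^2 / (se_a^4 / df_a + se_b^4 / df_b)
  p <- stats::pt(-abs(tstat), df) * if (tail == "two") 2 else 1
  structure(list(estimate_diff = est_a - est_b,
                 t = tstat, df = df, p = p, tail = tail),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Welch comparison: diff = %.4g, t = %.3f, df = %.2f, %s-tailed p = %.4g\n",
              x$estimate_diff, x$t, x$df, x$tail, x$p))
  invisible(x)
}

#' Residual-variance reduction test (predisposition criterion)
#'
#' Tests whether the residual variance of trained chicks about the
#' preference-score regression is reduced relative to the variance of
#' untrained chicks. One-tailed by default (only a reduction counts): the p
#' value is the upper-tail probability of an F variate with
#' `(df_untrained, df_residual)` degrees of freedom exceeding the observed
#' `untrained/residual` variance ratio.
#'
#' @param residual_variance Residual variance of the trained-chick
#'   regression (> 0).
#' @param df_residual Its degrees of freedom (the slope-df convention).
#' @param untrained_variance Sample variance of the untrained group (> 0).
#' @param df_untrained Its degrees of freedom (n_untrained - 1).
#' @param tail `"one_less"` (default: reduction only) or `"two"`.
#' @return An object of class `variance_test`: list with `ratio`
#'   (= residual/untrained), `df_num`, `df_den`, `p`, `tail`.
#' @export
residual_variance_test <- function(residual_variance, df_residual,
                                   untrained_variance, df_untrained,
                                   tail = c("one_less", "two")) {
  tail <- match.arg(tail)
  assert_number(residual_variance, "residual_variance")
  assert_number(untrained_variance, "untrained_variance")
  if (residual_variance <= 0 || untrained_variance <= 0) {
    stop_imprint("variances must be positive", "invalid_argument")
  }
  if (df_residual <= 0 || df_untrained <= 0) {
    stop_imprint("degrees of freedom must be positive", "invalid_argument")
  }
  f_obs <- untrained_variance / residual_variance
  p_one <- stats::pf(f_obs, df_untrained, df_residual, lower.tail = FALSE)
  p <- if (tail == "one_less") p_one else 2 * min(p_one, 1 - p_one)
  structure(list(ratio = residual_variance / untrained_variance,
                 df_num = df_untrained, df_den = df_residual,
                 p = p, tail = tail),
            class = "variance_test")
}

#' Total-variance homogeneity test
#'
#' Two-tailed F test of equality between the total variance of standardized
#' trained amounts (about their mean) and the untrained-group variance. Under
#' a predisposition the two should be homogeneous; a significant increase in
#' trained chicks argues against it.
#'
#' @param trained_total_variance Sample variance of standardized trained
#'   amounts (> 0).
#' @param df_trained Its degrees of freedom (n_trained - 1).
#' @param untrained_variance,df_untrained As in [residual_variance_test()].
#' @return An object of class `variance_test` with `ratio`
#'   (= trained/untrained), `df_num` (trained), `df_den` (untrained), `p`,
#'   `tail = "two"`.
#' @export
total_variance_test <- function(trained_total_variance, df_trained,
                                untrained_variance, df_untrained) {
  assert_number(trained_total_variance, "trained_total_variance")
  assert_number(untrained_variance, "untrained_variance")
  if (trained_total_variance <= 0 || untrained_variance <= 0) {
    stop_imprint("variances must be positive", "invalid_argument")
  }
  if (df_trained <= 0 || df_untrained <= 0) {
    stop_imprint("degrees of freedom must be positive", "invalid_argument")
  }
  f_obs <- trained_total_variance / untrained_variance
  p <- 2 * min(stats::pf(f_obs, df_trained, df_untrained),
               stats::pf(f_obs, df_trained, df_untrained, lower.tail = FALSE))
  p <- min(p, 1)
  structure(list(ratio = f_obs, df_num = df_trained, df_den = df_untrained,
                 p = p, tail = "two"),
            class = "variance_test")
}

#' @export
print.variance_test <- function(x, ...) {
  cat(sprintf("Variance ratio = %.4g (df %g, %g), %s-tailed p = %.4g\n",
              x$ratio, x$df_num, x$df_den, x$tail, x$p))
  invisible(x)
}

#' Classify one protein measure
#'
#' Applies the decision criteria to the full set of statistics for one
#' measure:
#' * a significant amount-vs-score correlation is the gate for any
#'   learning-related inference;
#' * **predisposition**: correlation significant, residual variance
#'   significantly reduced relative to untrained chicks (one-tailed), and
#'   trained total variance homogeneous with untrained;
#' * **learning-dependent**: correlation significant, *no* residual-variance
#'   reduction, and the level at the maximum preference score significantly
#'   different from the untrained mean;
#' * **training side-effect**: the level at score 50 (no learning) differs
#'   significantly from the untrained mean — an effect of training itself,
#'   assessable alongside either verdict;
#' * a significant correlation satisfying neither branch yields no flag, with
#'   an explanatory note (insufficient evidence).
#'
#' Marginal results (p < 0.1) are reported in the notes, never as flags.
#'
#' @param correlation List with `r`, `df`, `p` from [correlation_from_fit()].
#' @param cmp_max [welch_compare()] of the intercept at the maximum attained
#'   preference score vs the untrained mean.
#' @param cmp_50 [welch_compare()] of the intercept at score 50 vs the
#'   untrained mean.
#' @param res_var [residual_variance_test()] result.
#' @param tot_var [total_variance_test()] result.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param measure_key Optional label (e.g. "left IMM Total h24") carried into
#'   the result.
#' @return An object of class `classification_result`: flags
#'   `correlation_significant`, `learning_dependent`, `predisposition`,
#'   `training_side_effect`, `verdict_notes`, `alpha`, `n_tests` (number of p
#'   values consulted), and the supporting statistics.
#' @export
classify_measure <- function(correlation, cmp_max, cmp_50, res_var, tot_var,
                             alpha = 0.05, measure_key = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop_imprint("alpha must be a single number in (0, 1)", "invalid_argument")
  }
  stopifnot(inherits(cmp_max, "comparison_result"),
            inherits(cmp_50, "comparison_result"),
            inherits(res_var, "variance_test"),
            inherits(tot_var, "variance_test"))
  corr_sig <- correlation$p < alpha
  res_reduced <- res_var$p < alpha
  tot_homog <- tot_var$p >= alpha
  predisposition <- corr_sig && res_reduced && tot_homog
  learning <- corr_sig && !res_reduced && cmp_max$p < alpha
  side_effect <- cmp_50$p < alpha

  notes <- character(0)
  if (!corr_sig) {
    notes <- c(notes, "no significant correlation with preference score: no evidence of a learning-related change")
  } else if (predisposition) {
    notes <- c(notes, "significant correlation with reduced residual variance and homogeneous total variance: consistent with a predisposition to learn")
  } else if (learning) {
    notes <- c(notes, "significant correlation, residual variance not reduced, level at maximum score differs from untrained mean: learning-dependent change")
  } else {
    notes <- c(notes, "correlation significant but criteria for neither learning-dependence nor predisposition met: insufficient evidence")
  }
  if (side_effect) {
    notes <- c(notes, "level at score 50 differs from untrained mean: training side-effect unrelated to learning")
  }
  marginal <- c(
    if (!corr_sig && correlation$p < 0.1) "correlation",
    if (cmp_max$p >= alpha && cmp_max$p < 0.1) "comparison at maximum score",
    if (cmp_50$p >= alpha && cmp_50$p < 0.1) "comparison at score 50",
    if (!res_reduced && res_var$p < 0.1) "residual-variance reduction")
  if (length(marginal) > 0L) {
    notes <- c(notes, sprintf("marginal (p < 0.1): %s",
                              paste(marginal, collapse = ", ")))
  }
  structure(list(
    measure_key = measure_key,
    correlation_significant = corr_sig,
    learning_dependent = learning,
    predisposition = predisposition,
    training_side_effect = side_effect,
    verdict_notes = paste(notes, collapse = "; "),
    alpha = alpha,
    n_tests = 5L,
    supporting = list(correlation = correlation, cmp_max = cmp_max,
                      cmp_50 = cmp_50, res_var = res_var, tot_var = tot_var)
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  if (!is.null(x$measure_key)) cat(sprintf("Measure: %s\n", x$measure_key))
  cat(sprintf("  correlation significant: %s (p = %.4g)\n",
              x$correlation_significant, x$supporting$correlation$p))
  cat(sprintf("  learning-dependent: %s | predisposition: %s | training side-effect: %s\n",
              x$learning_dependent, x$predisposition, x$training_side_effect))
  cat(sprintf("  %s\n", x$verdict_notes))
  invisible(x)
}
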