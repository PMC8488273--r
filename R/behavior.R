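# Behavioural preference scoring and group-level summaries.
#
# The strength of imprinting is measured in a two-stimulus preference test:
# the chick approaches (in a running wheel) the familiar training stimulus and
# a novel alternative, and the preference score is the percentage of total
# test approach directed at the training stimulus. 50 means no preference
# (no learning), 100 means exclusive approach to the training stimulus.

#' Preference score from test approach distances
#'
#' Computes `100 * a_train / (a_train + a_alt)`, the percentage of total
#' approach during the preference test directed at the training stimulus.
#'
#' @param approach_train_stim Approach to the training stimulus during the
#'   test, in metres (nonnegative). Vectorised.
#' @param approach_alt_stim Approach to the alternative stimulus during the
#'   test, in metres (nonnegative). Vectorised.
#' @return Numeric vector of preference scores on \[0, 100\].
#' @details A chick that approaches neither stimulus has an undefined score;
#'   this raises an `undefined_score` error. Callers that must tolerate such
#'   chicks (e.g. the data loader) should exclude them first and log the
#'   exclusion.
#' @examples
#' preference_score(8, 8)     # 50: no preference
#' preference_score(5, 0)     # 100: exclusive preference
#' preference_score(7.5, 2.5) # 75
#' @export
preference_score <- function(approach_train_stim, approach_alt_stim) {
  if (length(approach_train_stim) != length(approach_alt_stim)) {
    stop_imprint("approach vectors must have equal length", "invalid_argument")
  }
  a <- as.numeric(approach_train_stim)
  b <- as.numeric(approach_alt_stim)
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stop_imprint("approach distances must be nonnegative", "invalid_argument")
  }
  tot <- a + b
  zero <- which(tot == 0)
  if (length(zero) > 0L) {
    stop_imprint(sprintf(
      "undefined preference score: total test approach is 0 (element %d)",
      zero[1L]), "undefined_score")
  }
  100 * a / tot
}

#' Convert running-wheel revolutions to metres
#'
#' Approach activity is recorded as wheel revolutions; one revolution
#' corresponds to 0.94 m of approach.
#'
#' @param revolutions Numeric vector of wheel revolutions.
#' @return Approach distance in metres.
#' @export
revolutions_to_metres <- function(revolutions) {
  0.94 * as.numeric(revolutions)
}

#' Group-level preference test against the no-preference score
#'
#' One-sample t test of the mean preference score against 50 (or another null
#' value), with the group mean and SEM. Two-tailed by default, matching the
#' convention used throughout the analysis.
#'
#' @param scores Numeric vector of preference scores (length >= 2).
#' @param null_score Null value tested against; default 50 (no preference).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param approach_training Optional vector of training-approach distances (m),
#'   summarised by its mean.
#' @param approach_testing Optional vector of total test-approach distances
#'   (m), summarised by its mean.
#' @return An object of class `behavior_summary`: list with `n`,
#'   `mean_preference`, `sem_preference`, `t_vs_null`, `df`, `p_vs_null`,
#'   `null_score`, `alternative`, `mean_approach_training`,
#'   `mean_approach_testing`.
#' @export
group_preference_test <- function(scores, null_score = 50,
                                  alternative = c("two.sided", "greater", "less"),
                                  approach_training = NULL,
                                  approach_testing = NULL) {
  alternative <- match.arg(alternative)
  scores <- as.numeric(scores)
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  if (n < 2L) {
    stop_imprint("at least 2 preference scores are required", "insufficient_data")
  }
  s <- stats::sd(scores)
  if (s == 0) {
    # t.test() refuses constant data; the limit is well defined.
    m <- scores[1L]
    tstat <- if (m == null_score) 0 else sign(m - null_score) * Inf
    p <- switch(alternative,
                two.sided = if (m == null_score) 1 else 0,
                greater = if (m > null_score) 0 else 1,
                less = if (m < null_score) 0 else 1)
    sem <- 0
  } else {
    tt <- stats::t.test(scores, mu = null_score, alternative = alternative)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
    sem <- s / sqrt(n)
    m <- unname(tt$estimate)
  }
  structure(list(
    n = n,
    mean_preference = m,
    sem_preference = sem,
    t_vs_null = tstat,
    df = n - 1L,
    p_vs_null = p,
    null_score = null_score,
    alternative = alternative,
    mean_approach_training =
      if (is.null(approach_training)) NA_real_ else mean(approach_training, na.rm = TRUE),
    mean_approach_testing =
      if (is.null(approach_testing)) NA_real_ else mean(approach_testing, na.rm = TRUE)
  ), class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("Preference summary: n = %d, mean = %.2f +/- %.2f (SEM)\n",
              x$n, x$mean_preference, x$sem_preference))
  cat(sprintf("t vs %s = %.3f (df %d), %s p = %.4g\n",
              format(x$null_score), x$t_vs_null, x$df, x$alternative,
              x$p_vs_null))
  invisible(x)
}
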