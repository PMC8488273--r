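# Batch standardization and the preference-score regression.
#
# Chicks hatch and are processed in batches (up to three trained plus one
# untrained control per hatch), and batch is modelled as a random intercept.
# The central model, fit to trained chicks only, is
#
#   amount_ij = alpha + beta * score_ij + u_j + e_ij,   u_j ~ N(0, sigma_b^2)
#
# estimated by REML. With one observation per chick the chick-within-batch
# random term is unidentifiable and is absorbed into the residual; replicate
# rows (replicate_id) re-enable it as ~1 | batch/chick.
#
# Degrees of freedom follow the convention df = n_chicks - n_batches - 1,
# which reproduces the published trained-chick dfs (21 chicks / 10 batches ->
# 10; 19 chicks / 9 batches -> 9).

#' Remove the estimated batch effect from per-chick values
#'
#' Subtracts (batch mean - overall mean) from each value, the "standardized"
#' scale used for summaries, variance comparisons and figures. The overall
#' mean is unchanged and the batch means of the output are all equal to it.
#'
#' @param values Numeric vector of per-chick values.
#' @param batch_ids Batch identifier per value.
#' @return Numeric vector of standardized values.
#' @export
standardize_by_batch <- function(values, batch_ids) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop_imprint("no values to standardize", "invalid_argument")
  }
  if (length(values) != length(batch_ids)) {
    stop_imprint("values and batch_ids must have equal length", "invalid_argument")
  }
  if (anyNA(values)) {
    stop_imprint("standardize_by_batch does not accept missing values",
                 "invalid_argument")
  }
  batch_means <- stats::ave(values, as.character(batch_ids))
  values - (batch_means - mean(values))
}

#' Mixed-effects regression of protein amount on preference score
#'
#' Fits, by REML (default), the trained-chick regression of relative protein
#' amount on preference score with a random batch intercept. With a single
#' batch the random term is unidentifiable and the fit reduces to ordinary
#' least squares with `var_batch = 0`. When `chick` identifiers with
#' replicate rows are supplied, the random structure becomes chick nested
#' within batch.
#'
#' @param amount Relative protein amounts (one per row).
#' @param score Preference scores (same length).
#' @param batch Batch identifiers (same length).
#' @param chick Optional chick identifiers; required only when chicks have
#'   replicate measurement rows.
#' @param reml Use REML (default) or maximum likelihood.
#' @return An object of class `pref_model_fit`: list with `intercept`,
#'   `slope`, `se_intercept`, `se_slope`, `cov_intercept_slope`, `df_slope`,
#'   `residual_variance`, `df_residual`, `var_batch`, `var_chick`, `n_obs`,
#'   `n_chicks`, `n_batches`, `method`, `engine`.
#' @details `df_slope = n_chicks - n_batches - 1` and `df_residual` follows
#'   the same convention, so that residual-variance comparisons use the df
#'   printed alongside the trained-chick correlations. Variance components
#'   estimated at the boundary are reported as 0 with a message.
#' @export
fit_preference_regression <- function(amount, score, batch, chick = NULL,
                                      reml = TRUE) {
  amount <- as.numeric(amount)
  score <- as.numeric(score)
  batch <- as.character(batch)
  n <- length(amount)
  if (length(score) != n || length(batch) != n) {
    stop_imprint("amount, score and batch must have equal length",
                 "invalid_argument")
  }
  if (anyNA(amount) || anyNA(score)) {
    stop_imprint("missing values in amount or score; drop incomplete chicks first",
                 "invalid_argument")
  }
  chick <- if (is.null(chick)) paste0("chick", seq_len(n)) else as.character(chick)
  n_chicks <- length(unique(chick))
  n_batches <- length(unique(batch))
  if (n_chicks < 3L) {
    stop_imprint("at least 3 trained chicks are required", "insufficient_data")
  }
  if (length(unique(score)) < 2L) {
    stop_imprint("all preference scores identical: slope unidentifiable",
                 "unidentifiable_slope")
  }
  replicated <- anyDuplicated(chick) > 0L
  method <- if (reml) "REML" else "ML"
  df_slope <- n_chicks - n_batches - 1L
  if (df_slope < 1L) {
    stop_imprint(sprintf(
      "df convention gives %d df for the slope (n_chicks %d, n_batches %d)",
      df_slope, n_chicks, n_batches), "insufficient_data")
  }

  if (n_batches == 1L && !replicated) {
    fit <- stats::lm(amount ~ score)
    V <- suppressWarnings(stats::vcov(fit))  # silence the perfect-fit warning
    co <- stats::coef(fit)
    sigma2 <- sum(stats::resid(fit)^2) / fit$df.residual
    var_batch <- 0
    var_chick <- 0
    engine <- "lm"
  } else {
    dat <- data.frame(amount = amount, score = score,
                      batch = factor(batch), chick = factor(chick))
    random <- if (replicated) ~ 1 | batch / chick else ~ 1 | batch
    fit <- nlme::lme(amount ~ score, random = random, data = dat,
                     method = method,
                     control = nlme::lmeControl(opt = "optim",
                                                returnObject = TRUE))
    co <- nlme::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    sigma2 <- fit$sigma^2
    vc <- suppressWarnings(nlme::VarCorr(fit))
    if (replicated) {
      var_batch <- as.numeric(vc[2L, 1L])
      var_chick <- as.numeric(vc[4L, 1L])
    } else {
      var_batch <- as.numeric(vc[1L, 1L])
      var_chick <- 0
    }
    engine <- "lme"
  }
  # lme's optimizer stops at tiny positive values when a component is really 0
  tot <- var_batch + var_chick + sigma2
  if (var_batch > 0 && var_batch < 1e-8 * tot) {
    message("fit_preference_regression: batch variance estimated at the boundary, reported as 0")
    var_batch <- 0
  }
  if (var_chick > 0 && var_chick < 1e-8 * tot) {
    var_chick <- 0
  }
  structure(list(
    intercept = unname(co[1L]),
    slope = unname(co[2L]),
    se_intercept = sqrt(V[1L, 1L]),
    se_slope = sqrt(V[2L, 2L]),
    cov_intercept_slope = V[1L, 2L],
    df_slope = df_slope,
    residual_variance = sigma2,
    df_residual = df_slope,
    var_batch = var_batch,
    var_chick = var_chick,
    n_obs = n,
    n_chicks = n_chicks,
    n_batches = n_batches,
    method = method,
    engine = engine
  ), class = "pref_model_fit")
}

#' @export
print.pref_model_fit <- function(x, ...) {
  cat(sprintf(
    "Preference regression (%s, %s): amount = %.4g + %.4g * score\n",
    x$engine, x$method, x$intercept, x$slope))
  cat(sprintf("  slope SE %.4g (df %d); residual var %.4g; batch var %.4g\n",
              x$se_slope, x$df_slope, x$residual_variance, x$var_batch))
  cat(sprintf("  n = %d chicks in %d batches\n", x$n_chicks, x$n_batches))
  invisible(x)
}

#' Correlation between protein amount and preference score from a model fit
#'
#' Converts the mixed-model slope t statistic into the within-batch
#' correlation reported alongside it: `r = sign(slope) * sqrt(t^2 / (t^2 +
#' df))`, with a two-tailed p from the t distribution. By construction the p
#' value equals the slope's t-test p value exactly.
#'
#' @param fit A [fit_preference_regression()] result.
#' @return List with `r`, `df`, `p`, `t`.
#' @export
correlation_from_fit <- function(fit) {
  stopifnot(inherits(fit, "pref_model_fit"))
  df <- fit$df_slope
  if (fit$se_slope == 0) {
    warning("slope standard error is 0; |r| = 1 and p = 0 by convention")
    r <- if (fit$slope == 0) 0 else sign(fit$slope)
    return(list(r = r, df = df, p = 0, t = sign(fit$slope) * Inf))
  }
  tstat <- fit$slope / fit$se_slope
  r <- sign(tstat) * sqrt(tstat^2 / (tstat^2 + df))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r = r, df = df, p = p, t = tstat)
}

#' Predicted protein level at a given preference score
#'
#' Evaluates the fitted regression line, with the delta-method standard error
#' `se^2 = se_int^2 + score^2 * se_slope^2 + 2 * score * cov(int, slope)`.
#' Used to estimate the protein level at score 50 (no learning) and at the
#' maximum attained score (strong learning).
#'
#' @param fit A [fit_preference_regression()] result.
#' @param score Preference score(s) at which to predict. Vectorised.
#' @return Data frame with columns `score`, `estimate`, `se`, `df`.
#' @export
predict_at_score <- function(fit, score) {
  stopifnot(inherits(fit, "pref_model_fit"))
  score <- as.numeric(score)
  est <- fit$intercept + fit$slope * score
  v <- fit$se_intercept^2 + score^2 * fit$se_slope^2 +
    2 * score * fit$cov_intercept_slope
  v[v < 0] <- 0  # guard against tiny negative rounding
  data.frame(score = score, estimate = est, se = sqrt(v), df = fit$df_slope)
}

#' Summary of untrained (control) chicks
#'
#' Mean, SEM, df and sample variance of the standardized relative amounts of
#' the untrained chicks: the comparator for the intercept tests and the
#' denominator of the variance-reduction criterion.
#'
#' @param values Standardized relative amounts for untrained chicks (n >= 2).
#' @return An object of class `group_summary`: list with `mean`, `sem`, `df`
#'   (= n - 1), `variance` (sample variance = n * sem^2), `n`.
#' @export
untrained_summary <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) {
    stop_imprint("at least 2 untrained chicks are required", "insufficient_data")
  }
  v <- stats::var(values)
  structure(list(mean = mean(values),
                 sem = sqrt(v / n),
                 df = n - 1L,
                 variance = v,
                 n = n),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group: n = %d, mean = %.4g +/- %.4g (SEM), df = %d, var = %.4g\n",
              x$n, x$mean, x$sem, x$df, x$variance))
  invisible(x)
}

#' Regression with training- and testing-approach covariates
#'
#' Refits the preference-score regression with approach during training and
#' approach during testing added as fixed covariates (same random batch
#' structure), and reports a marginal F statistic (numerator df 1) for each
#' fixed term with denominator df `n_chicks - n_batches - 3`.
#'
#' @param amount,score,batch,chick,reml As in [fit_preference_regression()].
#' @param approach_training Approach during training (m), per chick.
#' @param approach_testing Total approach during the preference test (m).
#' @return An object of class `pref_covariate_fit`: the fields of
#'   `pref_model_fit` (slope terms refer to preference score, adjusted for
#'   the covariates) plus `ftable`, a data frame with one row per fixed term
#'   (`term`, `coef`, `se`, `F`, `df1`, `df2`, `p`).
#' @details Covariates with zero variance cannot enter the design matrix;
#'   they are dropped with a message, which reduces the model to the plain
#'   preference regression for the remaining terms. Nearly collinear
#'   covariates trigger a condition-number warning.
#' @export
fit_with_approach_covariates <- function(amount, score, approach_training,
                                         approach_testing, batch, chick = NULL,
                                         reml = TRUE) {
  amount <- as.numeric(amount)
  n <- length(amount)
  covs <- list(score = as.numeric(score),
               approach_training = as.numeric(approach_training),
               approach_testing = as.numeric(approach_testing))
  if (any(vapply(covs, length, 1L) != n) || length(batch) != n) {
    stop_imprint("all inputs must have equal length", "invalid_argument")
  }
  if (anyNA(amount) || anyNA(covs$score)) {
    stop_imprint("missing amounts or scores; drop incomplete chicks first",
                 "invalid_argument")
  }
  if (anyNA(covs$approach_training) || anyNA(covs$approach_testing)) {
    stop_imprint("approach covariates must be available for all chicks used",
                 "invalid_argument")
  }
  batch <- as.character(batch)
  chick <- if (is.null(chick)) paste0("chick", seq_len(n)) else as.character(chick)
  n_chicks <- length(unique(chick))
  n_batches <- length(unique(batch))

  degenerate <- vapply(covs, function(v) stats::var(v) == 0, logical(1L))
  if (degenerate[["score"]]) {
    stop_imprint("all preference scores identical: slope unidentifiable",
                 "unidentifiable_slope")
  }
  used <- names(covs)[!degenerate]
  if (any(degenerate)) {
    message(sprintf("fit_with_approach_covariates: dropping constant covariate(s): %s",
                    paste(names(covs)[degenerate], collapse = ", ")))
  }
  X <- do.call(cbind, covs[used])
  if (length(used) > 1L) {
    kappa_x <- kappa(scale(X), exact = TRUE)
    if (!is.finite(kappa_x) || kappa_x > 1e6) {
      warning(sprintf(
        "approach covariates nearly collinear (condition number %.3g)", kappa_x))
    }
  }
  df_den <- n_chicks - n_batches - length(used)
  if (df_den < 1L) {
    stop_imprint("not enough chicks for the covariate model", "insufficient_data")
  }
  dat <- data.frame(amount = amount, batch = factor(batch),
                    chick = factor(chick), X)
  form <- stats::reformulate(used, response = "amount")
  replicated <- anyDuplicated(chick) > 0L
  if (n_batches == 1L && !replicated) {
    fit <- stats::lm(form, data = dat)
    co <- stats::coef(fit)
    V <- stats::vcov(fit)
    sigma2 <- sum(stats::resid(fit)^2) / fit$df.residual
    var_batch <- 0
    engine <- "lm"
  } else {
    random <- if (replicated) ~ 1 | batch / chick else ~ 1 | batch
    fit <- nlme::lme(form, random = random, data = dat,
                     method = if (reml) "REML" else "ML",
                     control = nlme::lmeControl(opt = "optim",
                                                returnObject = TRUE))
    co <- nlme::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    sigma2 <- fit$sigma^2
    vc <- suppressWarnings(nlme::VarCorr(fit))
    var_batch <- as.numeric(vc[1L, 1L])
    engine <- "lme"
  }
  terms <- names(covs)
  coefs <- ses <- rep(NA_real_, length(terms))
  names(coefs) <- names(ses) <- terms
  for (tm in used) {
    coefs[tm] <- co[[tm]]
    ses[tm] <- sqrt(V[tm, tm])
  }
  Fstat <- (coefs / ses)^2
  ftable <- data.frame(
    term = terms,
    coef = unname(coefs),
    se = unname(ses),
    F = unname(Fstat),
    df1 = 1L,
    df2 = df_den,
    p = unname(stats::pf(Fstat, 1, df_den, lower.tail = FALSE)),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(
    intercept = unname(co[1L]),
    slope = unname(coefs[["score"]]),
    se_intercept = sqrt(V[1L, 1L]),
    se_slope = unname(ses[["score"]]),
    cov_intercept_slope = V[1L, "score"],
    df_slope = df_den,
    residual_variance = sigma2,
    df_residual = df_den,
    var_batch = var_batch,
    var_chick = 0,
    n_obs = n,
    n_chicks = n_chicks,
    n_batches = n_batches,
    method = if (reml) "REML" else "ML",
    engine = engine,
    ftable = ftable
  ), class = c("pref_covariate_fit", "pref_model_fit"))
}

#' @export
print.pref_covariate_fit <- function(x, ...) {
  cat("Preference regression with approach covariates\n")
  print(x$ftable, digits = 4)
  invisible(x)
}
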