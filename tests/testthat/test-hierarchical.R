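test_that("batch standardization removes batch means and keeps the overall mean", {
  expect_equal(standardize_by_batch(c(5, 7), c("a", "a")), c(5, 7))
  expect_equal(standardize_by_batch(c(1, 1, 3, 3), c("a", "a", "b", "b")),
               rep(2, 4))
  set.seed(31)
  v <- rnorm(12, 10, 2)
  b <- rep(c("a", "b", "c"), each = 4)
  out <- standardize_by_batch(v, b)
  expect_equal(mean(out), mean(v), tolerance = 1e-12)
  means <- tapply(out, b, mean)
  expect_equal(as.vector(means), rep(mean(v), 3), tolerance = 1e-12)
  expect_error(standardize_by_batch(numeric(0), character(0)),
               class = "invalid_argument")
})

test_that("noiseless data recover the generating line exactly", {
  score <- c(55, 60, 70, 80, 95)
  fit <- fit_preference_regression(2 + 0.01 * score, score, rep("b1", 5))
  expect_equal(fit$slope, 0.01, tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-8)
  expect_equal(fit$residual_variance, 0, tolerance = 1e-16)
  expect_equal(fit$var_batch, 0)
  expect_equal(fit$df_slope, 3L)  # 5 chicks, 1 batch
})

test_that("single-batch fits equal the closed-form least-squares oracle", {
  set.seed(17)
  score <- runif(12, 40, 100)
  y <- 1 + 0.008 * score + rnorm(12, 0, 0.15)
  fit <- fit_preference_regression(y, score, rep("b1", 12))
  or <- ols_oracle(score, y)
  expect_equal(fit$slope, or$slope, tolerance = 1e-8)
  expect_equal(fit$intercept, or$intercept, tolerance = 1e-8)
  expect_equal(fit$se_slope, or$se_slope, tolerance = 1e-8)
  expect_equal(fit$cov_intercept_slope, or$cov, tolerance = 1e-8)
  expect_equal(fit$var_batch, 0)
})

test_that("the mixed fit with negligible batch variance matches OLS on multi-batch data", {
  set.seed(23)
  n <- 18
  score <- runif(n, 40, 100)
  batch <- rep(paste0("b", 1:6), each = 3)
  y <- 1 + 0.005 * score + rnorm(n, 0, 0.1)  # no true batch effect
  fit <- suppressMessages(fit_preference_regression(y, score, batch))
  or <- ols_oracle(score, y)
  # REML pushes the batch variance to (near) zero and the fixed effects to OLS
  expect_lt(fit$var_batch, 0.02 * fit$residual_variance + 1e-8)
  expect_equal(fit$slope, or$slope, tolerance = 0.05)
  expect_equal(fit$df_slope, n - 6L - 1L)
})

test_that("the published df convention holds for the two study designs", {
  for (spec in list(list(preset = "paper-like-1h", chicks = 21L, batches = 10L, df = 10L),
                    list(preset = "paper-like-24h", chicks = 19L, batches = 9L, df = 9L))) {
    cfg <- scenario_presets(spec$preset, scenario = "null", seed = 99)
    dat <- generate_experiment(cfg)
    tr <- dat$chicks[dat$chicks$trained, ]
    expect_equal(nrow(tr), spec$chicks)
    expect_equal(length(unique(tr$batch_id)), spec$batches)
    amt <- dat$measurements$relative_amount[match(tr$chick_id,
                                                  dat$measurements$chick_id)]
    fit <- fit_preference_regression(amt, tr$preference_score, tr$batch_id)
    expect_equal(fit$df_slope, spec$df)
    expect_equal(correlation_from_fit(fit)$df, spec$df)
  }
})

test_that("degenerate regressions are rejected", {
  expect_error(fit_preference_regression(1:2, c(50, 60), c("a", "a")),
               class = "insufficient_data")
  expect_error(fit_preference_regression(c(1, 2, 3), rep(70, 3), rep("a", 3)),
               class = "unidentifiable_slope")
})

test_that("correlation derives from the slope t statistic with matching p", {
  fit <- structure(list(slope = 0, se_slope = 0.01, df_slope = 10L),
                   class = "pref_model_fit")
  co <- correlation_from_fit(fit)
  expect_equal(co$r, 0)
  expect_equal(co$p, 1)

  # r = 0.748 with 9 df corresponds to p = 0.008 (published correlation row)
  t9 <- 0.748 * sqrt(9 / (1 - 0.748^2))
  fit <- structure(list(slope = t9, se_slope = 1, df_slope = 9L),
                   class = "pref_model_fit")
  co <- correlation_from_fit(fit)
  expect_equal(co$r, 0.748, tolerance = 1e-12)
  expect_equal(co$p, 0.008, tolerance = 0.0005 / 0.008)  # printed precision

  # sign symmetry
  fit_neg <- structure(list(slope = -t9, se_slope = 1, df_slope = 9L),
                       class = "pref_model_fit")
  expect_equal(correlation_from_fit(fit_neg)$p, co$p)
  expect_equal(correlation_from_fit(fit_neg)$r, -co$r)

  # p equals the slope t-test p exactly, by construction
  set.seed(3)
  y <- rnorm(12); s <- runif(12, 40, 100)
  f <- fit_preference_regression(y, s, rep("b", 12))
  cc <- correlation_from_fit(f)
  expect_identical(cc$p, 2 * pt(-abs(f$slope / f$se_slope), f$df_slope))
})

test_that("predictions at a score match the delta-method quadratic form", {
  set.seed(13)
  cfg <- scenario_presets("paper-like-1h", scenario = "learning", seed = 13)
  dat <- generate_experiment(cfg)
  tr <- dat$chicks[dat$chicks$trained, ]
  amt <- dat$measurements$relative_amount[match(tr$chick_id,
                                                dat$measurements$chick_id)]
  fit <- fit_preference_regression(amt, tr$preference_score, tr$batch_id)
  for (s in c(0, 50, 100)) {
    p <- predict_at_score(fit, s)
    expect_equal(p$estimate, fit$intercept + s * fit$slope)
    # quadratic form x' V x with x = (1, s)
    V <- matrix(c(fit$se_intercept^2, fit$cov_intercept_slope,
                  fit$cov_intercept_slope, fit$se_slope^2), 2)
    expect_equal(p$se, sqrt(drop(t(c(1, s)) %*% V %*% c(1, s))),
                 tolerance = 1e-10)
    expect_equal(p$df, fit$df_slope)
  }
  p0 <- predict_at_score(fit, 0)
  expect_equal(p0$se, fit$se_intercept)

  exact <- fit_preference_regression(2 + 0.01 * c(55, 60, 70, 80, 95),
                                     c(55, 60, 70, 80, 95), rep("b1", 5))
  pe <- predict_at_score(exact, 100)
  expect_equal(pe$estimate, 3, tolerance = 1e-8)
  expect_equal(pe$se, 0, tolerance = 1e-7)
})

test_that("untrained summaries report mean, SEM, df and variance consistently", {
  s <- untrained_summary(c(1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$sem, 0)
  expect_equal(s$df, 2L)

  set.seed(19)
  v <- rnorm(10, 1, 0.2)
  s <- untrained_summary(v)
  expect_equal(s$df, 9L)
  expect_equal(s$variance, s$n * s$sem^2, tolerance = 1e-12)
  expect_error(untrained_summary(1), class = "insufficient_data")
})

test_that("replicate rows enable the chick-within-batch random term", {
  set.seed(29)
  n_chick <- 12
  chick <- rep(paste0("c", 1:n_chick), each = 3)
  batch <- rep(rep(paste0("b", 1:4), each = 3), each = 3)
  score <- rep(runif(n_chick, 40, 100), each = 3)
  y <- 1 + 0.005 * score + rep(rnorm(4, 0, 0.1), each = 9) +
    rep(rnorm(n_chick, 0, 0.15), each = 3) + rnorm(3 * n_chick, 0, 0.05)
  fit <- fit_preference_regression(y, score, batch, chick = chick)
  expect_gt(fit$var_chick, 0)
  expect_equal(fit$df_slope, n_chick - 4L - 1L)
  expect_equal(fit$n_obs, 36L)
})

test_that("approach covariates: degenerate covariates reduce to the plain fit", {
  set.seed(37)
  cfg <- scenario_presets("paper-like-1h", scenario = "learning", seed = 37)
  dat <- generate_experiment(cfg)
  tr <- dat$chicks[dat$chicks$trained, ]
  amt <- dat$measurements$relative_amount[match(tr$chick_id,
                                                dat$measurements$chick_id)]
  plain <- fit_preference_regression(amt, tr$preference_score, tr$batch_id)
  withcov <- suppressMessages(fit_with_approach_covariates(
    amt, tr$preference_score, rep(0, nrow(tr)), rep(0, nrow(tr)), tr$batch_id))
  expect_equal(withcov$slope, plain$slope, tolerance = 1e-8)
  expect_equal(withcov$se_slope, plain$se_slope, tolerance = 1e-8)
  expect_true(all(is.na(withcov$ftable$F[withcov$ftable$term != "score"])))

  # full model: 21 chicks, 10 batches, 3 fixed terms -> denominator df 8
  full <- fit_with_approach_covariates(
    amt, tr$preference_score, tr$approach_training_m,
    tr$approach_test_train_m + tr$approach_test_alt_m, tr$batch_id)
  expect_equal(unique(full$ftable$df2), 8L)
  expect_equal(full$ftable$df1, rep(1L, 3))
  # marginal F is the squared coefficient t ratio
  expect_equal(full$ftable$F,
               (full$ftable$coef / full$ftable$se)^2, tolerance = 1e-12)
})

test_that("a testing-approach effect is detected as such, not as a score effect", {
  # amounts driven by testing approach only: its F should be significant far
  # more often than the preference-score F
  hits_testing <- 0L
  hits_score <- 0L
  n_sim <- 60L
  for (i in seq_len(n_sim)) {
    cfg <- scenario_presets("paper-like-1h", scenario = "null", seed = 500 + i)
    dat <- generate_experiment(cfg)
    tr <- dat$chicks[dat$chicks$trained, ]
    testing <- tr$approach_test_train_m + tr$approach_test_alt_m
    set.seed(9000 + i)
    amt <- 1 + 0.03 * testing + rnorm(nrow(tr), 0, 0.1)
    f <- fit_with_approach_covariates(amt, tr$preference_score,
                                      tr$approach_training_m, testing,
                                      tr$batch_id)
    ps <- setNames(f$ftable$p, f$ftable$term)
    hits_testing <- hits_testing + (ps[["approach_testing"]] < 0.05)
    hits_score <- hits_score + (ps[["score"]] < 0.05)
  }
  expect_gte(hits_testing / n_sim, 0.9)
  expect_lte(hits_score / n_sim, 0.2)
})
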