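test_that("scenario presets match the two study designs and reject unknown names", {
  c1 <- scenario_presets("paper-like-1h")
  expect_equal(c1$n_batches, 10L)
  expect_equal(sum(c1$trained_per_batch), 21L)
  expect_equal(c1$timepoint, "h1")
  c2 <- scenario_presets("paper-like-24h")
  expect_equal(c2$n_batches, 9L)
  expect_equal(sum(c2$trained_per_batch), 19L)
  expect_error(scenario_presets("paper-like-2h"), class = "unknown_preset",
               regexp = "paper-like-1h")
})

test_that("scenario parameters outside their scenario are forced to zero", {
  cfg <- scenario_config("null", learning_slope = 0.02, side_effect_shift = 1,
                         aptitude_sd = 0.5, seed = 1)
  expect_equal(cfg$learning_slope, 0)
  expect_equal(cfg$side_effect_shift, 0)
  expect_equal(cfg$aptitude_sd, 0)
  combined <- scenario_config("learning", side_effect_shift = 0.3,
                              combine = TRUE, seed = 1)
  expect_equal(combined$side_effect_shift, 0.3)
  expect_error(scenario_config("null", n_batches = 3, trained_per_batch = c(4, 1, 1)),
               class = "invalid_config")
})

test_that("the same seed reproduces the experiment bit for bit", {
  cfg <- scenario_presets("paper-like-1h", scenario = "predisposition", seed = 77)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(a$chicks, b$chicks)
  expect_identical(a$measurements, b$measurements)
  cfg2 <- scenario_presets("paper-like-1h", scenario = "predisposition", seed = 78)
  expect_false(identical(generate_experiment(cfg2)$measurements, a$measurements))
})

test_that("noiseless learning data lie exactly on the generative line", {
  cfg <- scenario_config("learning", batch_sd = 0, residual_sd = 0,
                         score_noise_sd = 22, seed = 5)
  dat <- generate_experiment(cfg)
  ch <- dat$chicks
  amt <- dat$measurements$relative_amount[match(ch$chick_id,
                                                dat$measurements$chick_id)]
  tr <- ch$trained
  expect_equal(amt[tr], 1 + 0.01 * (ch$preference_score[tr] - 50),
               tolerance = 1e-12)
  expect_equal(amt[!tr], rep(1, sum(!tr)), tolerance = 1e-12)
})

test_that("generated approaches are consistent with the generated scores", {
  cfg <- scenario_presets("paper-like-1h", scenario = "learning", seed = 10)
  dat <- generate_experiment(cfg)
  tr <- dat$chicks[dat$chicks$trained, ]
  expect_equal(preference_score(tr$approach_test_train_m, tr$approach_test_alt_m),
               tr$preference_score, tolerance = 1e-12)
  un <- dat$chicks[!dat$chicks$trained, ]
  expect_true(all(is.na(un$preference_score)))
})

test_that("strong aptitude-to-score gain makes score track aptitude", {
  cfg <- scenario_config("predisposition", n_batches = 10L,
                         trained_per_batch = rep(3L, 10L),
                         score_noise_sd = 0.1, score_mean = 50, seed = 42)
  dat <- generate_experiment(cfg)
  d <- dat$metadata$truth$aptitude
  tr <- dat$chicks$trained
  keep <- tr & dat$chicks$preference_score > 0 & dat$chicks$preference_score < 100
  expect_gt(cor(d[keep], dat$chicks$preference_score[keep]), 0.99)
})

test_that("predisposition makes trained and untrained amounts exchangeable and cuts residual variance", {
  # large synthetic cohort: sample analogues of the population identities
  cfg <- scenario_config("predisposition", n_batches = 400L,
                         trained_per_batch = rep(2L, 400L),
                         batch_sd = 0, seed = 31)
  dat <- generate_experiment(cfg)
  ch <- dat$chicks
  amt <- dat$measurements$relative_amount[match(ch$chick_id,
                                                dat$measurements$chick_id)]
  tr <- ch$trained
  # no training effect on the protein: equal means and variances
  expect_lt(abs(mean(amt[tr]) - mean(amt[!tr])), 0.03)
  expect_lt(abs(var(amt[tr]) / var(amt[!tr]) - 1), 0.25)
  # residual variance about the score regression is far below untrained variance
  ols <- lm(amt[tr] ~ ch$preference_score[tr])
  resid_var <- sum(resid(ols)^2) / ols$df.residual
  rho2 <- cor(ch$preference_score[tr], amt[tr])^2
  expect_lt(resid_var / var(amt[!tr]), 0.5)
  expect_equal(resid_var / var(amt[tr]), 1 - rho2, tolerance = 0.02)
})

test_that("in the learning scenario the expected amount at score 50 is the untrained mean", {
  cfg <- scenario_config("learning", n_batches = 500L,
                         trained_per_batch = rep(2L, 500L),
                         batch_sd = 0, seed = 8)
  dat <- generate_experiment(cfg)
  ch <- dat$chicks
  amt <- dat$measurements$relative_amount[match(ch$chick_id,
                                                dat$measurements$chick_id)]
  fit <- lm(amt[ch$trained] ~ I(ch$preference_score[ch$trained] - 50))
  expect_equal(unname(coef(fit)[1]), mean(amt[!ch$trained]), tolerance = 0.03)
})

test_that("zero-noise densitometry round-trips relative amounts for any gain", {
  cfg <- scenario_presets("paper-like-1h", scenario = "learning", seed = 14,
                          measures = c("Total", "P416"))
  dat <- generate_experiment(cfg)
  dens <- generate_densitometry(dat, densitometry_config(), seed = 14)
  out <- apply_calibration(dens$samples, dens$standards)
  key <- function(df) paste(df$chick_id, df$measure)
  truth <- dat$measurements$relative_amount[match(key(out), key(dat$measurements))]
  expect_equal(out$relative_amount, truth, tolerance = 1e-10)
  # gains genuinely differ across gels yet amounts agree
  gains <- tapply(dens$standards$od[dens$standards$micrograms == 30],
                  dens$standards$gel_id[dens$standards$micrograms == 30], mean)
  expect_gt(diff(range(gains)), 0.1)
})

test_that("mild densitometry noise keeps recovered amounts close to truth", {
  ok <- 0L; total <- 0L
  for (i in 1:20) {
    cfg <- scenario_presets("paper-like-1h", scenario = "null", seed = 100 + i)
    dat <- generate_experiment(cfg)
    dens <- generate_densitometry(dat, densitometry_config(od_noise_cv = 0.02),
                                  seed = 200 + i)
    out <- suppressMessages(
      apply_calibration(dens$samples, dens$standards, linearity_threshold = 0))
    truth <- dat$measurements$relative_amount[match(out$chick_id,
                                                    dat$measurements$chick_id)]
    ok <- ok + sum(abs(out$relative_amount / truth - 1) < 0.1)
    total <- total + length(truth)
  }
  expect_gte(ok / total, 0.95)
})
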