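# Shared fixtures: tiny hand-built experiments used across test files.
# Everything is generated in code; nothing is stored on disk.

# Two batches, two trained + one untrained chick each, one measure.
make_tiny_experiment <- function() {
  chicks <- data.frame(
    chick_id = c("c1", "c2", "c3", "c4", "c5", "c6"),
    batch_id = c("b1", "b1", "b1", "b2", "b2", "b2"),
    trained = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    approach_training_m = c(50, 60, NA, 40, 80, NA),
    approach_test_train_m = c(9, 6, NA, 7.5, 8, NA),
    approach_test_alt_m = c(3, 2, NA, 2.5, 8, NA),
    preference_score = c(75, 75, NA, 75, 50, NA),
    stringsAsFactors = FALSE)
  meas <- expand.grid(chick_id = chicks$chick_id, measure = c("Total", "P416", "P527"),
                      stringsAsFactors = FALSE)
  meas$region <- "IMM"
  meas$hemisphere <- "left"
  meas$relative_amount <- seq(0.5, by = 0.1, length.out = nrow(meas))
  experiment_data(chicks, meas, timepoint = "h1")
}

write_experiment_files <- function(data, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  b <- file.path(dir, "behavior.csv")
  m <- file.path(dir, "measurements.csv")
  write_experiment(data, b, m)
  list(behavior = b, measurements = m, dir = dir)
}

# Closed-form simple linear regression (normal equations): the independent
# oracle for least-squares fits.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  list(slope = slope, intercept = intercept, sigma2 = s2,
       se_slope = sqrt(s2 / sxx),
       se_intercept = sqrt(s2 * (1 / n + mean(x)^2 / sxx)),
       cov = -s2 * mean(x) / sxx)
}
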