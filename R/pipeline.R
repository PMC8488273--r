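# End-to-end orchestration: one analysis block per (region, hemisphere,
# measure), mirroring the published table layout, plus the Monte-Carlo
# operating-characteristics driver.

RESULT_NUMERIC_COLS <- c(
  "n_untrained", "untrained_mean", "untrained_sem", "untrained_df",
  "untrained_variance", "n_trained", "n_batches",
  "correlation_r", "correlation_df", "correlation_p",
  "slope", "se_slope", "intercept", "se_intercept",
  "residual_variance", "df_residual", "var_batch",
  "max_score", "est_at_max", "se_at_max",
  "t_max_vs_untrained", "df_max_vs_untrained", "p_max_vs_untrained",
  "est_at_50", "se_at_50",
  "t_50_vs_untrained", "df_50_vs_untrained", "p_50_vs_untrained",
  "resid_var_ratio", "resid_var_p",
  "total_var_ratio", "total_var_p",
  "f_score", "f_approach_training", "f_approach_testing",
  "f_df2", "p_f_score", "p_f_approach_training", "p_f_approach_testing",
  "n_tests")
RESULT_LOGICAL_COLS <- c("correlation_significant", "learning_dependent",
                         "predisposition", "training_side_effect")
RESULT_KEY_COLS <- c("region", "hemisphere", "measure", "timepoint")
RESULT_CHAR_COLS <- c("notes", "error")

empty_results_row <- function() {
  row <- as.data.frame(
    c(stats::setNames(as.list(rep(NA_character_, length(RESULT_KEY_COLS))),
                      RESULT_KEY_COLS),
      stats::setNames(as.list(rep(NA_real_, length(RESULT_NUMERIC_COLS))),
                      RESULT_NUMERIC_COLS),
      stats::setNames(as.list(rep(NA, length(RESULT_LOGICAL_COLS))),
                      RESULT_LOGICAL_COLS),
      stats::setNames(as.list(rep(NA_character_, length(RESULT_CHAR_COLS))),
                      RESULT_CHAR_COLS)),
    stringsAsFactors = FALSE)
  row
}

#' Run the full analysis on an experiment
#'
#' For every (region, hemisphere, measure) present: derives ratio measures,
#' standardizes relative amounts by batch, summarises the untrained group,
#' fits the mixed-effects preference-score regression to the trained chicks,
#' derives the correlation, predicts the protein level at score 50 and at the
#' maximum attained score, compares both against the untrained mean
#' (Welch-Satterthwaite), runs the residual- and total-variance tests, and
#' classifies the measure. Each block is analysed independently; a failure in
#' one block is recorded in its `error` column and the remaining blocks still
#' run.
#'
#' @param data An `experiment_data` object.
#' @param alpha Significance level (default 0.05).
#' @param max_score Score treated as "strong learning" for the upper
#'   intercept; default `NULL` uses the maximum observed trained score (100
#'   in the published experiments).
#' @param batch_mean_scope `"all"` (default): batch means for standardization
#'   use trained and untrained chicks together; `"trained_only"` restricts
#'   them to trained chicks.
#' @param covariates If `TRUE`, additionally fit the approach-covariate model
#'   per block and report its marginal F statistics.
#' @param reml Use REML (default) for the mixed fits.
#' @param derive_ratios Derive the three ratio measures before analysis
#'   (default `TRUE`).
#' @return A `results_table`: data frame with one row per analysed block and
#'   the statistics in published-table order, with the classification flags
#'   and notes appended. Attributes: `config` (resolved options), `log`
#'   (dropped chicks and messages), `n_tests_total`.
#' @details The regression is fit to the raw relative amounts with a random
#'   batch intercept; the batch-standardized amounts (which have the same
#'   overall mean) provide the untrained summary, the trained total variance
#'   and the published plotting scale. Fitting the regression to standardized
#'   amounts instead would bias the slope towards zero, because
#'   standardization removes between-batch variation from the response but
#'   not from the scores.
#' @export
run_analysis <- function(data, alpha = 0.05, max_score = NULL,
                         batch_mean_scope = c("all", "trained_only"),
                         covariates = FALSE, reml = TRUE,
                         derive_ratios = TRUE) {
  stopifnot(inherits(data, "experiment_data"))
  batch_mean_scope <- match.arg(batch_mean_scope)
  if (derive_ratios) data <- derive_ratio_measures(data)
  ch <- data$chicks
  me <- data$measurements
  me <- me[!is.na(me$relative_amount), , drop = FALSE]
  # replicate rows are averaged per chick unless an explicit replicate model
  # is wanted; singleton data pass through unchanged
  me <- stats::aggregate(relative_amount ~ chick_id + region + hemisphere + measure,
                         data = me, FUN = mean)
  idx <- match(me$chick_id, ch$chick_id)
  me$batch_id <- ch$batch_id[idx]
  me$trained <- ch$trained[idx]
  me$score <- ch$preference_score[idx]
  me$approach_training <- ch$approach_training_m[idx]
  me$approach_testing <- ch$approach_test_train_m[idx] + ch$approach_test_alt_m[idx]

  blocks <- unique(me[, c("region", "hemisphere", "measure")])
  blocks <- blocks[order(blocks$region, blocks$hemisphere,
                         match(blocks$measure, c(BASE_MEASURES, RATIO_MEASURES))), ,
                   drop = FALSE]
  log <- character(0)
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    g <- me[me$region == b$region & me$hemisphere == b$hemisphere &
              me$measure == b$measure, , drop = FALSE]
    row <- empty_results_row()
    row$region <- b$region
    row$hemisphere <- b$hemisphere
    row$measure <- b$measure
    row$timepoint <- data$timepoint

    missing_chicks <- setdiff(ch$chick_id, g$chick_id)
    if (length(missing_chicks) > 0L) {
      log <<- c(log, sprintf("%s/%s/%s: dropped chick(s) lacking the measure: %s",
                             b$region, b$hemisphere, b$measure,
                             paste(missing_chicks, collapse = ", ")))
    }
    std_source <- if (batch_mean_scope == "all") g else g[g$trained, , drop = FALSE]
    batch_means <- tapply(std_source$relative_amount, std_source$batch_id, mean)
    overall <- mean(std_source$relative_amount)
    known <- g$batch_id %in% names(batch_means)
    if (!all(known)) {
      log <<- c(log, sprintf("%s/%s/%s: no batch mean for chick(s) %s",
                             b$region, b$hemisphere, b$measure,
                             paste(g$chick_id[!known], collapse = ", ")))
      g <- g[known, , drop = FALSE]
    }
    g$standardized <- g$relative_amount - (batch_means[g$batch_id] - overall)

    un <- g[!g$trained, , drop = FALSE]
    tr <- g[g$trained, , drop = FALSE]
    row$n_untrained <- nrow(un)
    row$n_trained <- nrow(tr)
    row$n_batches <- length(unique(tr$batch_id))

    if (nrow(un) >= 2L) {
      us <- untrained_summary(un$standardized)
      row$untrained_mean <- us$mean
      row$untrained_sem <- us$sem
      row$untrained_df <- us$df
      row$untrained_variance <- us$variance
    }

    res <- tryCatch({
      if (nrow(tr) == 0L) {
        stop_imprint("no trained chicks", "insufficient_data")
      }
      if (nrow(un) < 2L) {
        stop_imprint("fewer than 2 untrained chicks", "insufficient_data")
      }
      undefined <- is.na(tr$score)
      if (any(undefined)) {
        log <<- c(log, sprintf("%s/%s/%s: excluded trained chick(s) with undefined score: %s",
                               b$region, b$hemisphere, b$measure,
                               paste(tr$chick_id[undefined], collapse = ", ")))
        tr <- tr[!undefined, , drop = FALSE]
      }
      fit <- fit_preference_regression(tr$relative_amount, tr$score,
                                       tr$batch_id, reml = reml)
      if (fit$var_batch == 0) {
        log <<- c(log, sprintf("%s/%s/%s: batch variance estimated as 0",
                               b$region, b$hemisphere, b$measure))
      }
      corr <- correlation_from_fit(fit)
      smax <- max_score %||% max(tr$score)
      pred <- predict_at_score(fit, c(50, smax))
      us <- untrained_summary(un$standardized)
      cmp50 <- welch_compare(pred$estimate[1L], pred$se[1L], pred$df[1L],
                             us$mean, us$sem, us$df)
      cmpmax <- welch_compare(pred$estimate[2L], pred$se[2L], pred$df[2L],
                              us$mean, us$sem, us$df)
      rv <- residual_variance_test(fit$residual_variance, fit$df_residual,
                                   us$variance, us$df)
      tv <- total_variance_test(stats::var(tr$standardized), nrow(tr) - 1L,
                                us$variance, us$df)
      cls <- classify_measure(corr, cmpmax, cmp50, rv, tv, alpha = alpha,
                              measure_key = sprintf("%s %s %s %s", b$hemisphere,
                                                    b$region, b$measure,
                                                    data$timepoint))
      row$correlation_r <- corr$r
      row$correlation_df <- corr$df
      row$correlation_p <- corr$p
      row$slope <- fit$slope
      row$se_slope <- fit$se_slope
      row$intercept <- fit$intercept
      row$se_intercept <- fit$se_intercept
      row$residual_variance <- fit$residual_variance
      row$df_residual <- fit$df_residual
      row$var_batch <- fit$var_batch
      row$max_score <- smax
      row$est_at_max <- pred$estimate[2L]
      row$se_at_max <- pred$se[2L]
      row$t_max_vs_untrained <- cmpmax$t
      row$df_max_vs_untrained <- cmpmax$df
      row$p_max_vs_untrained <- cmpmax$p
      row$est_at_50 <- pred$estimate[1L]
      row$se_at_50 <- pred$se[1L]
      row$t_50_vs_untrained <- cmp50$t
      row$df_50_vs_untrained <- cmp50$df
      row$p_50_vs_untrained <- cmp50$p
      row$resid_var_ratio <- rv$ratio
      row$resid_var_p <- rv$p
      row$total_var_ratio <- tv$ratio
      row$total_var_p <- tv$p
      row$correlation_significant <- cls$correlation_significant
      row$learning_dependent <- cls$learning_dependent
      row$predisposition <- cls$predisposition
      row$training_side_effect <- cls$training_side_effect
      row$notes <- cls$verdict_notes
      row$n_tests <- cls$n_tests

      if (covariates && !anyNA(tr$approach_training) &&
          !anyNA(tr$approach_testing)) {
        cf <- fit_with_approach_covariates(tr$relative_amount, tr$score,
                                           tr$approach_training,
                                           tr$approach_testing,
                                           tr$batch_id, reml = reml)
        ft <- cf$ftable
        row$f_score <- ft$F[ft$term == "score"]
        row$f_approach_training <- ft$F[ft$term == "approach_training"]
        row$f_approach_testing <- ft$F[ft$term == "approach_testing"]
        row$f_df2 <- ft$df2[1L]
        row$p_f_score <- ft$p[ft$term == "score"]
        row$p_f_approach_training <- ft$p[ft$term == "approach_training"]
        row$p_f_approach_testing <- ft$p[ft$term == "approach_testing"]
        row$n_tests <- row$n_tests + 3L
      }
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    res
  })
  out <- do.call(rbind, rows)
  for (col in RESULT_NUMERIC_COLS) out[[col]] <- as.numeric(out[[col]])
  class(out) <- c("results_table", "data.frame")
  attr(out, "config") <- list(alpha = alpha, max_score = max_score,
                              batch_mean_scope = batch_mean_scope,
                              covariates = covariates, reml = reml,
                              df_convention = "n_chicks - n_batches - 1",
                              timepoint = data$timepoint)
  attr(out, "log") <- log
  attr(out, "n_tests_total") <- sum(out$n_tests, na.rm = TRUE)
  out
}

#' @export
print.results_table <- function(x, ...) {
  cat(sprintf("results_table: %d measure block(s), alpha = %g\n",
              nrow(x), attr(x, "config")$alpha %||% NA))
  cols <- c(RESULT_KEY_COLS, "correlation_r", "correlation_p",
            "learning_dependent", "predisposition", "training_side_effect")
  print.data.frame(x[, intersect(cols, names(x))], digits = 4, row.names = FALSE)
  if (any(!is.na(x$error))) {
    cat("Blocks with errors:\n")
    print.data.frame(x[!is.na(x$error), c(RESULT_KEY_COLS, "error")],
                     row.names = FALSE)
  }
  invisible(x)
}

#' Monte-Carlo operating characteristics of the classification pipeline
#'
#' Repeats generate -> analyse -> classify under a scenario configuration and
#' aggregates the rates at which each criterion fires, together with slope
#' recovery diagnostics. Deterministic given the master seed; per-replicate
#' failures are counted, not fatal.
#'
#' @param cfg A [scenario_config()] (its `seed` is ignored; per-replicate
#'   seeds are derived from `seed`).
#' @param replicates Number of replicate experiments (>= 1).
#' @param seed Master seed for the study.
#' @param alpha Significance level passed to [run_analysis()].
#' @return An object of class `operating_characteristics`: list with
#'   `scenario`, `replicates`, `n_failed`, `rates` (data frame criterion /
#'   rate / mc_se, where mc_se = sqrt(p(1-p)/reps)), `slope_mean`,
#'   `slope_true`, `ci_coverage` (95% t-interval coverage of the true slope),
#'   `seed`, and the per-replicate data frame `reps`.
#' @export
run_simulation_study <- function(cfg, replicates, seed = NULL, alpha = 0.05) {
  stopifnot(inherits(cfg, "scenario_config"))
  replicates <- as.integer(replicates)
  if (replicates < 1L) {
    stop_imprint("replicates must be >= 1", "invalid_argument")
  }
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates)
  beta_true <- cfg$learning_slope
  per_rep <- lapply(seq_len(replicates), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- rep_seeds[i]
    tryCatch({
      dat <- generate_experiment(cfg_i)
      res <- run_analysis(dat, alpha = alpha, derive_ratios = FALSE)
      r1 <- res[1L, ]
      if (!is.na(r1$error)) stop(r1$error)
      tcrit <- stats::qt(0.975, r1$correlation_df)
      data.frame(
        seed = rep_seeds[i],
        correlation_significant = r1$correlation_significant,
        learning_dependent = r1$learning_dependent,
        predisposition = r1$predisposition,
        training_side_effect = r1$training_side_effect,
        slope = r1$slope,
        se_slope = r1$se_slope,
        ci_covers = (r1$slope - tcrit * r1$se_slope) <= beta_true &
          (r1$slope + tcrit * r1$se_slope) >= beta_true,
        failed = FALSE)
    }, error = function(e) {
      data.frame(seed = rep_seeds[i], correlation_significant = NA,
                 learning_dependent = NA, predisposition = NA,
                 training_side_effect = NA, slope = NA_real_,
                 se_slope = NA_real_, ci_covers = NA, failed = TRUE)
    })
  })
  reps <- do.call(rbind, per_rep)
  ok <- !reps$failed
  n_ok <- sum(ok)
  rate <- function(flag) {
    p <- mean(flag[ok])
    c(rate = p, mc_se = sqrt(p * (1 - p) / max(n_ok, 1L)))
  }
  rates <- t(vapply(c("correlation_significant", "learning_dependent",
                      "predisposition", "training_side_effect"),
                    function(cn) rate(reps[[cn]]), numeric(2L)))
  rates <- data.frame(criterion = rownames(rates), rate = rates[, 1L],
                      mc_se = rates[, 2L], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(
    scenario = cfg$scenario,
    replicates = replicates,
    n_failed = sum(reps$failed),
    rates = rates,
    slope_mean = mean(reps$slope[ok]),
    slope_true = beta_true,
    ci_coverage = mean(reps$ci_covers[ok]),
    alpha = alpha,
    seed = seed,
    reps = reps
  ), class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("Operating characteristics: scenario '%s', %d replicates (%d failed)\n",
              x$scenario, x$replicates, x$n_failed))
  print.data.frame(x$rates, digits = 3, row.names = FALSE)
  cat(sprintf("slope mean %.5g (true %.5g), 95%% CI coverage %.3f\n",
              x$slope_mean, x$slope_true, x$ci_coverage))
  invisible(x)
}
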