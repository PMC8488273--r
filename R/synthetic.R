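# Synthetic-experiment generator.
#
# Emulates the batch-structured imprinting design — about ten hatch batches,
# up to three trained chicks plus one untrained control per batch — under
# four generative scenarios for a protein measure y with batch effects
# u_b ~ N(0, sigma_b^2), per-chick aptitude d ~ N(0, sigma_d^2) and residual
# noise e ~ N(0, sigma_eps^2):
#
#   untrained:  y = mu0 + u_b + gamma * d + e          (gamma = 1 only under
#                                                       predisposition)
#   trained:    s = clamp(mu_s + kappa * d + eta, 0, 100),
#               eta ~ N(0, sigma_s^2)
#               y = mu0 + u_b + delta + beta * (s - 50) + gamma * d + e
#
# beta != 0 only in the learning scenario, delta != 0 only in side_effect,
# and (gamma, kappa) only in predisposition, unless scenarios are explicitly
# combined. Everything is deterministic given the seed.

#' Scenario configuration for the synthetic generator
#'
#' @param scenario One of `"null"`, `"learning"`, `"side_effect"`,
#'   `"predisposition"`.
#' @param n_batches Number of hatch batches (default 10).
#' @param trained_per_batch Integer vector (1-3 per batch) of trained chicks
#'   per batch; default `c(3, 2, 2, ...)` totalling 21 trained chicks over 10
#'   batches. Each batch additionally gets one untrained control.
#' @param baseline Baseline relative amount mu0 (default 1.0).
#' @param batch_sd Between-batch SD sigma_b of the amount (default 0.15).
#' @param residual_sd Residual SD sigma_eps of the amount (default 0.2; 0.1
#'   under `predisposition`, giving the canonical aptitude-to-residual sd
#'   ratio of 2).
#' @param learning_slope Amount change per score unit (beta); default 0.01
#'   in the `learning` scenario (about +0.5 relative amount between score 50
#'   and 100), 0 otherwise.
#' @param side_effect_shift Training-induced amount shift delta; default
#'   0.25 in the `side_effect` scenario, 0 otherwise.
#' @param aptitude_sd SD sigma_d of the latent aptitude contribution to the
#'   amount; default 0.2 in the `predisposition` scenario, 0 otherwise.
#' @param score_gain Score units per aptitude unit (kappa); default 100 in
#'   `predisposition`, 0 otherwise.
#' @param score_noise_sd SD of score noise eta; default 22 (matching the
#'   observed spread of preference scores), 4 under `predisposition` where
#'   most score variation comes from aptitude.
#' @param score_mean Mean preference score (default 72).
#' @param combine If `FALSE` (default), parameters belonging to other
#'   scenarios are forced to their null values; set `TRUE` to mix effects.
#' @param region,hemisphere,measures Labels for the generated measurements;
#'   several `measures` share batch effects and aptitude but have
#'   independent residuals.
#' @param timepoint `"h1"` or `"h24"`.
#' @param seed Integer seed; same seed, same dataset, bit for bit.
#' @return An object of class `scenario_config` (validated list).
#' @export
scenario_config <- function(scenario = c("null", "learning", "side_effect",
                                         "predisposition"),
                            n_batches = 10L,
                            trained_per_batch = NULL,
                            baseline = 1.0,
                            batch_sd = 0.15,
                            residual_sd = NULL,
                            learning_slope = NULL,
                            side_effect_shift = NULL,
                            aptitude_sd = NULL,
                            score_gain = NULL,
                            score_noise_sd = NULL,
                            score_mean = 72,
                            combine = FALSE,
                            region = "IMM",
                            hemisphere = "left",
                            measures = "Total",
                            timepoint = "h1",
                            seed = NULL) {
  scenario <- match.arg(scenario)
  n_batches <- as.integer(n_batches)
  if (n_batches < 1L) stop_imprint("n_batches must be >= 1", "invalid_config")
  if (is.null(trained_per_batch)) {
    trained_per_batch <- default_trained_pattern(n_batches, 21L)
  }
  trained_per_batch <- as.integer(trained_per_batch)
  if (length(trained_per_batch) != n_batches ||
      any(trained_per_batch < 1L | trained_per_batch > 3L)) {
    stop_imprint("trained_per_batch must give 1-3 trained chicks for each batch",
                 "invalid_config")
  }
  residual_sd <- residual_sd %||%
    if (scenario == "predisposition") 0.1 else 0.2
  learning_slope <- learning_slope %||%
    if (scenario == "learning") 0.01 else 0
  side_effect_shift <- side_effect_shift %||%
    if (scenario == "side_effect") 0.25 else 0
  aptitude_sd <- aptitude_sd %||%
    if (scenario == "predisposition") 0.2 else 0
  score_gain <- score_gain %||%
    if (scenario == "predisposition") 100 else 0
  score_noise_sd <- score_noise_sd %||%
    if (scenario == "predisposition") 4 else 22
  if (!combine) {
    if (scenario != "learning") learning_slope <- 0
    if (scenario != "side_effect") side_effect_shift <- 0
    if (scenario != "predisposition") {
      aptitude_sd <- 0
      score_gain <- 0
    }
  }
  for (nm in c("batch_sd", "residual_sd", "aptitude_sd", "score_noise_sd")) {
    assert_number(get(nm), nm, lower = 0)
  }
  assert_number(baseline, "baseline")
  assert_number(learning_slope, "learning_slope")
  assert_number(side_effect_shift, "side_effect_shift")
  assert_number(score_gain, "score_gain")
  assert_number(score_mean, "score_mean", 0, 100)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop_imprint("seed must be an integer", "invalid_config")
  }
  structure(list(
    scenario = scenario, n_batches = n_batches,
    trained_per_batch = trained_per_batch, baseline = baseline,
    batch_sd = batch_sd, residual_sd = residual_sd,
    learning_slope = learning_slope, side_effect_shift = side_effect_shift,
    aptitude_sd = aptitude_sd, score_gain = score_gain,
    score_noise_sd = score_noise_sd, score_mean = score_mean,
    combine = combine, region = region, hemisphere = hemisphere,
    measures = measures, timepoint = match.arg(timepoint, TIMEPOINTS),
    seed = seed
  ), class = "scenario_config")
}

# 21 trained over 10 batches -> c(3, 2, 2, ...); general n: fill 2s then 3s/1s
default_trained_pattern <- function(n_batches, total) {
  base <- rep(2L, n_batches)
  excess <- total - sum(base)
  i <- 1L
  while (excess != 0L && i <= n_batches) {
    step <- sign(excess)
    if (base[i] + step >= 1L && base[i] + step <= 3L) {
      base[i] <- base[i] + step
      excess <- excess - step
    }
    i <- i + 1L
  }
  if (excess != 0L) {
    stop_imprint("cannot distribute trained chicks at 1-3 per batch",
                 "invalid_config")
  }
  base
}

#' Named scenario presets matching the published study designs
#'
#' `"paper-like-1h"`: 10 batches, 21 trained + 10 untrained chicks (the 1 h
#' sampling design); `"paper-like-24h"`: 9 batches, 19 trained + 9 untrained
#' (the 24 h design).
#'
#' @param name Preset name.
#' @param scenario Generative scenario for the preset (default `"null"`).
#' @param ... Further overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_presets <- function(name, scenario = "null", ...) {
  presets <- list(
    `paper-like-1h` = list(n_batches = 10L,
                           trained_per_batch = default_trained_pattern(10L, 21L),
                           timepoint = "h1"),
    `paper-like-24h` = list(n_batches = 9L,
                            trained_per_batch = default_trained_pattern(9L, 19L),
                            timepoint = "h24"))
  if (!name %in% names(presets)) {
    stop_imprint(sprintf("unknown preset '%s'; available: %s", name,
                         paste(names(presets), collapse = ", ")),
                 "unknown_preset")
  }
  args <- utils::modifyList(c(presets[[name]], list(scenario = scenario)),
                            list(...))
  do.call(scenario_config, args)
}

#' Generate a synthetic experiment
#'
#' Draws a complete experiment (behaviour table plus measurements) under the
#' configured scenario. Trained chicks' test approaches are generated so that
#' the preference-score formula recovers the generated score exactly.
#'
#' @param cfg A [scenario_config()].
#' @return A validated `experiment_data`; `metadata$truth` records the
#'   scenario, all generative parameters, and the per-chick latent aptitude.
#' @export
generate_experiment <- function(cfg) {
  if (!inherits(cfg, "scenario_config")) {
    stop_imprint("cfg must be a scenario_config", "invalid_config")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nb <- cfg$n_batches
  per_batch <- cfg$trained_per_batch + 1L
  batch <- rep(seq_len(nb), per_batch)
  trained <- unlist(lapply(cfg$trained_per_batch,
                           function(k) c(rep(TRUE, k), FALSE)))
  n <- length(batch)
  chick_id <- sprintf("b%02d_c%d", batch,
                      unlist(lapply(per_batch, seq_len)))
  batch_id <- sprintf("batch%02d", batch)

  u <- stats::rnorm(nb, 0, cfg$batch_sd)[batch]
  d <- stats::rnorm(n, 0, cfg$aptitude_sd)
  gamma <- if (cfg$aptitude_sd > 0) 1 else 0

  score <- rep(NA_real_, n)
  idx <- which(trained)
  raw_score <- cfg$score_mean + cfg$score_gain * d[idx] +
    stats::rnorm(length(idx), 0, cfg$score_noise_sd)
  score[idx] <- pmin(100, pmax(0, raw_score))

  # Approach distances consistent with the scores by construction.
  approach_training <- rep(NA_real_, n)
  approach_test_total <- rep(NA_real_, n)
  approach_training[idx] <- stats::rlnorm(length(idx), log(55), 0.6)
  approach_test_total[idx] <- stats::rlnorm(length(idx), log(12), 0.5)
  approach_test_train <- score / 100 * approach_test_total
  approach_test_alt <- approach_test_total - approach_test_train

  chicks <- data.frame(
    chick_id = chick_id, batch_id = batch_id, trained = trained,
    approach_training_m = approach_training,
    approach_test_train_m = approach_test_train,
    approach_test_alt_m = approach_test_alt,
    preference_score = score,
    stringsAsFactors = FALSE)

  meas <- do.call(rbind, lapply(cfg$measures, function(m) {
    e <- stats::rnorm(n, 0, cfg$residual_sd)
    y <- cfg$baseline + u + gamma * d + e
    y[idx] <- y[idx] + cfg$side_effect_shift +
      cfg$learning_slope * (score[idx] - 50)
    data.frame(chick_id = chick_id, region = cfg$region,
               hemisphere = cfg$hemisphere, measure = m,
               relative_amount = y, stringsAsFactors = FALSE)
  }))

  experiment_data(
    chicks, meas, timepoint = cfg$timepoint,
    metadata = list(truth = c(unclass(cfg)[setdiff(names(cfg), "seed")],
                              list(seed = cfg$seed, aptitude = d,
                                   batch_effects = u))))
}

#' Densitometry simulation configuration
#'
#' @param gain_range Positive interval from which each gel's multiplicative
#'   gain (film exposure x antibody sensitivity) is drawn uniformly; default
#'   `c(0.5, 2)`.
#' @param od_noise_cv Optical-density noise SD as a fraction of the signal
#'   (default 0: noise-free).
#' @param standards Standard protein amounts loaded on each gel, in ug;
#'   default `c(15, 30, 45, 60)`.
#' @return An object of class `densitometry_config`.
#' @export
densitometry_config <- function(gain_range = c(0.5, 2), od_noise_cv = 0,
                                standards = DEFAULT_STANDARDS) {
  if (length(gain_range) != 2L || any(gain_range <= 0) ||
      gain_range[1L] > gain_range[2L]) {
    stop_imprint("gain_range must be a positive interval", "invalid_config")
  }
  assert_number(od_noise_cv, "od_noise_cv", lower = 0)
  standards <- as.numeric(standards)
  if (length(standards) < 2L || any(standards <= 0)) {
    stop_imprint("at least 2 positive standard amounts are required",
                 "invalid_config")
  }
  structure(list(gain_range = gain_range, od_noise_cv = od_noise_cv,
                 standards = standards),
            class = "densitometry_config")
}

#' Simulate per-gel standards and sample optical densities
#'
#' Gives every (batch, measure) its own gel with a random multiplicative
#' gain: standard OD = gain * micrograms / 30, sample OD = gain * relative
#' amount, both optionally perturbed by proportional noise. Calibrating and
#' normalising the output recovers the generated relative amounts up to that
#' noise, for any gain.
#'
#' @param data An `experiment_data` whose measurements provide the true
#'   relative amounts.
#' @param dcfg A [densitometry_config()].
#' @param seed Optional integer seed.
#' @return List with `standards` (gel_id, micrograms, od) and `samples`
#'   (chick_id, region, hemisphere, measure, gel_id, od), ready for
#'   [apply_calibration()] / [load_experiment()].
#' @export
generate_densitometry <- function(data, dcfg = densitometry_config(),
                                  seed = NULL) {
  stopifnot(inherits(data, "experiment_data"),
            inherits(dcfg, "densitometry_config"))
  if (!is.null(seed)) set.seed(seed)
  me <- data$measurements
  batch_of <- stats::setNames(data$chicks$batch_id, data$chicks$chick_id)
  gel_id <- paste(me$measure, batch_of[me$chick_id], sep = "_")
  gels <- unique(gel_id)
  gain <- stats::setNames(
    stats::runif(length(gels), dcfg$gain_range[1L], dcfg$gain_range[2L]), gels)

  noisy <- function(signal) {
    if (dcfg$od_noise_cv == 0) return(signal)
    pmax(signal + stats::rnorm(length(signal), 0, dcfg$od_noise_cv * signal), 0)
  }
  standards <- do.call(rbind, lapply(gels, function(g) {
    data.frame(gel_id = g, micrograms = dcfg$standards,
               od = noisy(gain[[g]] * dcfg$standards / 30),
               stringsAsFactors = FALSE)
  }))
  samples <- data.frame(
    chick_id = me$chick_id, region = me$region, hemisphere = me$hemisphere,
    measure = me$measure, gel_id = gel_id,
    od = noisy(gain[gel_id] * me$relative_amount),
    stringsAsFactors = FALSE, row.names = NULL)
  list(standards = standards, samples = samples)
}
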