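# Domain types and long-format IO.
#
# An experiment is two tidy tables joined on chick_id:
#   chicks:        chick_id, batch_id, trained, approach_training_m,
#                  approach_test_train_m, approach_test_alt_m, preference_score
#   measurements:  chick_id, region, hemisphere, measure, relative_amount
#                  (+ optional replicate_id)
# Each hatch batch contributes up to three trained chicks and one untrained
# control; four tissue samples (left/right IMM, left/right PPN) come from
# each chick, and each sample yields one relative amount per protein measure.

BASE_MEASURES <- c("Total", "P416", "P527")
RATIO_MEASURES <- c("P416_over_Total", "P527_over_Total", "P527_over_P416")
REGIONS <- c("IMM", "PPN")
HEMISPHERES <- c("left", "right")
TIMEPOINTS <- c("h1", "h24")

CHICK_COLUMNS <- c("chick_id", "batch_id", "trained", "approach_training_m",
                   "approach_test_train_m", "approach_test_alt_m",
                   "preference_score")

#' Construct a validated experiment dataset
#'
#' Bundles the per-chick behaviour table and the long-format measurement table
#' into a single validated object used by the whole pipeline.
#'
#' @param chicks Data frame with columns `chick_id`, `batch_id`, `trained`
#'   (logical) and, for trained chicks, `approach_training_m`,
#'   `approach_test_train_m`, `approach_test_alt_m` (metres) and
#'   `preference_score` (derived if absent).
#' @param measurements Data frame with columns `chick_id`, `region`
#'   (`"IMM"`/`"PPN"`), `hemisphere` (`"left"`/`"right"`), `measure` (one of
#'   `Total`, `P416`, `P527` or a derived ratio), `relative_amount` (> 0), and
#'   optionally `replicate_id`.
#' @param timepoint `"h1"` or `"h24"`: time of tissue sampling after training.
#' @param metadata Free-form named list carried through the pipeline.
#' @param check_batches If `TRUE` (default), require every batch to contain at
#'   least one trained and exactly one untrained chick.
#' @param score_tolerance Maximum allowed discrepancy (score units) between a
#'   stated preference score and the score recomputed from the two test
#'   approaches; default 0.5 (scores are conventionally reported to 1
#'   decimal).
#' @param allow_ratios If `FALSE` (default for loaded files), reject ratio
#'   measures in `measurements`: ratios are always derived, never read.
#' @return An object of class `experiment_data`.
#' @seealso [load_experiment()], [derive_ratio_measures()]
#' @export
experiment_data <- function(chicks, measurements, timepoint = "h1",
                            metadata = list(), check_batches = TRUE,
                            score_tolerance = 0.5, allow_ratios = TRUE) {
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  chicks <- as.data.frame(chicks, stringsAsFactors = FALSE)
  measurements <- as.data.frame(measurements, stringsAsFactors = FALSE)
  require_columns(chicks, c("chick_id", "batch_id", "trained"), "behaviour table")
  require_columns(measurements,
                  c("chick_id", "region", "hemisphere", "measure", "relative_amount"),
                  "measurement table")
  for (col in setdiff(CHICK_COLUMNS, names(chicks))) chicks[[col]] <- NA_real_
  chicks$chick_id <- as.character(chicks$chick_id)
  chicks$batch_id <- as.character(chicks$batch_id)
  measurements$chick_id <- as.character(measurements$chick_id)
  measurements$region <- as.character(measurements$region)
  measurements$hemisphere <- as.character(measurements$hemisphere)
  measurements$measure <- as.character(measurements$measure)
  if (!"replicate_id" %in% names(measurements)) {
    measurements$replicate_id <- NA_character_
  }
  x <- structure(list(chicks = chicks,
                      measurements = measurements,
                      timepoint = timepoint,
                      metadata = metadata),
                 class = "experiment_data")
  validate_experiment_data(x, check_batches = check_batches,
                           score_tolerance = score_tolerance,
                           allow_ratios = allow_ratios)
}

#' Validate an experiment dataset
#'
#' Checks the structural invariants of the design: trained/untrained field
#' patterns, preference-score consistency with the test approaches, batch
#' composition, measurement uniqueness, and positivity of relative amounts.
#' Trained chicks with zero total test approach get an undefined preference
#' score: they are set to `NA`, recorded under `metadata$undefined_score`, and
#' later dropped from regression analyses.
#'
#' @inheritParams experiment_data
#' @param x An `experiment_data` object.
#' @return `x`, possibly with derived preference scores filled in.
#' @export
validate_experiment_data <- function(x, check_batches = TRUE,
                                     score_tolerance = 0.5,
                                     allow_ratios = TRUE) {
  ch <- x$chicks
  me <- x$measurements
  if (anyDuplicated(ch$chick_id)) {
    stop_imprint("duplicated chick_id in behaviour table", "duplication_error")
  }
  if (!is.logical(ch$trained)) {
    ch$trained <- parse_logical(ch$trained, "trained", "behaviour table")
  }
  for (col in c("approach_training_m", "approach_test_train_m",
                "approach_test_alt_m", "preference_score")) {
    ch[[col]] <- parse_numeric(as.character(ch[[col]]), col, "behaviour table")
  }
  me$relative_amount <- parse_numeric(as.character(me$relative_amount),
                                      "relative_amount", "measurement table")

  untr <- !ch$trained
  bad <- untr & (!is.na(ch$preference_score) |
                   !is.na(ch$approach_training_m) |
                   !is.na(ch$approach_test_train_m) |
                   !is.na(ch$approach_test_alt_m))
  if (any(bad)) {
    stop_imprint(sprintf(
      "untrained chick(s) carry preference/approach fields: %s",
      paste(ch$chick_id[bad], collapse = ", ")), "validation_error")
  }

  appr <- !is.na(ch$approach_test_train_m) & !is.na(ch$approach_test_alt_m)
  zero_tot <- appr & (ch$approach_test_train_m + ch$approach_test_alt_m) == 0
  if (any(zero_tot)) {
    x$metadata$undefined_score <-
      union(x$metadata$undefined_score, ch$chick_id[zero_tot])
    ch$preference_score[zero_tot] <- NA_real_
  }
  ok <- appr & !zero_tot
  if (any(ok)) {
    recomputed <- preference_score(ch$approach_test_train_m[ok],
                                   ch$approach_test_alt_m[ok])
    stated <- ch$preference_score[ok]
    mism <- !is.na(stated) & abs(stated - recomputed) > score_tolerance
    if (any(mism)) {
      stop_imprint(sprintf(
        "preference score inconsistent with test approaches (>%.2g units) for chick(s): %s",
        score_tolerance,
        paste(ch$chick_id[ok][mism], collapse = ", ")), "validation_error")
    }
    ch$preference_score[ok][is.na(stated)] <- recomputed[is.na(stated)]
  }
  ps <- ch$preference_score
  if (any(!is.na(ps) & (ps < 0 | ps > 100))) {
    stop_imprint("preference score outside [0, 100]", "validation_error")
  }

  if (check_batches) {
    tab <- table(ch$batch_id, factor(ch$trained, levels = c(FALSE, TRUE)))
    bad_b <- rownames(tab)[tab[, "TRUE"] < 1L | tab[, "FALSE"] != 1L]
    if (length(bad_b) > 0L) {
      stop_imprint(sprintf(
        "batch(es) without >=1 trained and exactly 1 untrained chick: %s",
        paste(bad_b, collapse = ", ")), "validation_error")
    }
  }

  if (!all(me$region %in% REGIONS)) {
    stop_imprint(sprintf("unknown region(s): %s",
                         paste(setdiff(me$region, REGIONS), collapse = ", ")),
                 "validation_error")
  }
  if (!all(me$hemisphere %in% HEMISPHERES)) {
    stop_imprint(sprintf("unknown hemisphere(s): %s",
                         paste(setdiff(me$hemisphere, HEMISPHERES), collapse = ", ")),
                 "validation_error")
  }
  known <- c(BASE_MEASURES, RATIO_MEASURES)
  if (!all(me$measure %in% known)) {
    stop_imprint(sprintf("unknown measure(s): %s",
                         paste(setdiff(me$measure, known), collapse = ", ")),
                 "validation_error")
  }
  if (!allow_ratios && any(me$measure %in% RATIO_MEASURES)) {
    stop_imprint("ratio measures are derived, never read from file",
                 "validation_error")
  }
  orphan <- setdiff(me$chick_id, ch$chick_id)
  if (length(orphan) > 0L) {
    stop_imprint(sprintf("measurement(s) for unknown chick(s): %s",
                         paste(orphan, collapse = ", ")), "validation_error")
  }
  key <- paste(me$chick_id, me$region, me$hemisphere, me$measure,
               ifelse(is.na(me$replicate_id), "", me$replicate_id))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_imprint(sprintf(
      "duplicated measurement for (chick, region, hemisphere, measure): %s", dup),
      "duplication_error")
  }
  if (any(!is.na(me$relative_amount) & me$relative_amount <= 0)) {
    stop_imprint("relative amounts must be positive", "validation_error")
  }

  x$chicks <- ch
  x$measurements <- me
  x
}

#' @export
print.experiment_data <- function(x, ...) {
  cat(sprintf(
    "experiment_data: %d chicks (%d trained) in %d batches, %d measurements, timepoint %s\n",
    nrow(x$chicks), sum(x$chicks$trained),
    length(unique(x$chicks$batch_id)), nrow(x$measurements), x$timepoint))
  invisible(x)
}

#' Load an experiment from behaviour and measurement tables
#'
#' Reads the two CSV/TSV tables (delimiter auto-detected unless given),
#' validates them, and optionally converts raw optical densities to relative
#' amounts via a per-gel calibration-standards table.
#'
#' @param behavior_file Path to the behaviour table: columns `chick_id`,
#'   `batch_id`, `trained`, and for trained chicks `approach_training_m`,
#'   `approach_test_train_m`, `approach_test_alt_m`, optionally
#'   `preference_score` (checked against the approaches when both present).
#' @param measurements_file Path to the measurement table: columns `chick_id`,
#'   `region`, `hemisphere`, `measure`, and either `relative_amount` or
#'   (`gel_id`, `od`) when `calibration_file` is supplied.
#' @param timepoint `"h1"` or `"h24"`.
#' @param calibration_file Optional path to a standards table (`gel_id`,
#'   `micrograms`, `od`) used to convert measurement ODs to relative amounts.
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @param check_batches,score_tolerance Passed to [experiment_data()].
#' @param through_origin,linearity_threshold Passed to [apply_calibration()]
#'   when a calibration table is used.
#' @return A validated `experiment_data` object (ratio measures not yet
#'   derived; see [derive_ratio_measures()]).
#' @export
load_experiment <- function(behavior_file, measurements_file, timepoint = "h1",
                            calibration_file = NULL, delim = NULL,
                            check_batches = TRUE, score_tolerance = 0.5,
                            through_origin = FALSE, linearity_threshold = 0.95) {
  chicks <- read_table_file(behavior_file, delim)
  meas <- read_table_file(measurements_file, delim)
  if (!is.null(calibration_file)) {
    require_columns(meas, c("gel_id", "od"), "measurement table")
    standards <- read_table_file(calibration_file, delim)
    standards$micrograms <- parse_numeric(standards$micrograms, "micrograms",
                                          "standards table")
    standards$od <- parse_numeric(standards$od, "od", "standards table")
    meas$od <- parse_numeric(meas$od, "od", "measurement table")
    meas <- apply_calibration(meas, standards, through_origin = through_origin,
                              linearity_threshold = linearity_threshold)
  }
  experiment_data(chicks, meas, timepoint = timepoint,
                  metadata = list(behavior_file = behavior_file,
                                  measurements_file = measurements_file),
                  check_batches = check_batches,
                  score_tolerance = score_tolerance,
                  allow_ratios = FALSE)
}

#' Derive ratio measures from the base protein forms
#'
#' Adds, per (chick, region, hemisphere, replicate) where all of `Total`,
#' `P416` and `P527` are present, the three ratio rows `P416_over_Total`,
#' `P527_over_Total` and `P527_over_P416`. Chicks missing a component get no
#' ratio rows and are reported; zero denominators are skipped, never turned
#' into infinities. Idempotent: rows whose ratio already exists are not added
#' again.
#'
#' @param data An `experiment_data` object.
#' @return `data` with ratio rows appended; attribute `"ratio_log"` on the
#'   measurement table lists sample keys skipped for missing components or
#'   zero denominators.
#' @export
derive_ratio_measures <- function(data) {
  stopifnot(inherits(data, "experiment_data"))
  me <- data$measurements
  base <- me[me$measure %in% BASE_MEASURES, , drop = FALSE]
  key <- interaction(base$chick_id, base$region, base$hemisphere,
                     ifelse(is.na(base$replicate_id), "", base$replicate_id),
                     drop = TRUE)
  existing <- paste(me$chick_id, me$region, me$hemisphere,
                    ifelse(is.na(me$replicate_id), "", me$replicate_id),
                    me$measure)
  added <- list()
  skipped <- character(0)
  for (k in levels(key)) {
    grp <- base[key == k, , drop = FALSE]
    amounts <- stats::setNames(grp$relative_amount, grp$measure)
    if (!all(BASE_MEASURES %in% names(amounts)) || anyNA(amounts[BASE_MEASURES])) {
      skipped <- c(skipped, sprintf("%s (missing component)", k))
      next
    }
    ratios <- c(P416_over_Total = unname(amounts["P416"] / amounts["Total"]),
                P527_over_Total = unname(amounts["P527"] / amounts["Total"]),
                P527_over_P416 = unname(amounts["P527"] / amounts["P416"]))
    denom0 <- !is.finite(ratios)
    if (any(denom0)) {
      skipped <- c(skipped, sprintf("%s (zero denominator: %s)", k,
                                    paste(names(ratios)[denom0], collapse = ", ")))
      ratios <- ratios[!denom0]
    }
    for (m in names(ratios)) {
      row_key <- paste(grp$chick_id[1L], grp$region[1L], grp$hemisphere[1L],
                       ifelse(is.na(grp$replicate_id[1L]), "", grp$replicate_id[1L]),
                       m)
      if (row_key %in% existing) next
      added[[length(added) + 1L]] <- data.frame(
        chick_id = grp$chick_id[1L], region = grp$region[1L],
        hemisphere = grp$hemisphere[1L], measure = m,
        relative_amount = ratios[[m]],
        replicate_id = grp$replicate_id[1L],
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped) > 0L) {
    message(sprintf("derive_ratio_measures: %d sample(s) without ratio rows",
                    length(skipped)))
  }
  if (length(added) > 0L) {
    me <- rbind(me[, c("chick_id", "region", "hemisphere", "measure",
                       "relative_amount", "replicate_id")],
                do.call(rbind, added))
  }
  attr(me, "ratio_log") <- skipped
  data$measurements <- me
  data
}

#' Write the behaviour and measurement tables of an experiment
#'
#' Convenience inverse of [load_experiment()]: writes the two tidy CSVs
#' (and nothing else) so a dataset can be re-loaded exactly.
#'
#' @param data An `experiment_data` object.
#' @param behavior_file,measurements_file Output paths.
#' @param digits Significant digits used to format numbers; default 17
#'   round-trips doubles exactly.
#' @return Invisibly, the two paths.
#' @export
write_experiment <- function(data, behavior_file, measurements_file,
                             digits = 17L) {
  stopifnot(inherits(data, "experiment_data"))
  ch <- data$chicks
  for (col in c("approach_training_m", "approach_test_train_m",
                "approach_test_alt_m", "preference_score")) {
    ch[[col]] <- fmt_num(ch[[col]], digits)
  }
  me <- data$measurements
  me$relative_amount <- fmt_num(me$relative_amount, digits)
  utils::write.csv(ch, behavior_file, row.names = FALSE, quote = FALSE)
  utils::write.csv(me, measurements_file, row.names = FALSE, quote = FALSE)
  invisible(c(behavior_file, measurements_file))
}
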