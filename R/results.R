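# Results-table serialisation.
#
# The on-disk layout mirrors the published tables: one column per measure
# block and one row per statistic (untrained mean/SEM/DF, correlation/DF/P,
# the two intercepts with SEs, the two Welch comparisons, the variance
# ratios), followed by the classification flags and notes. Numbers are
# written with a configurable significant-digit precision (the default, 17,
# round-trips doubles exactly), so write -> read is lossless.

results_block_label <- function(x) {
  paste(x$region, x$hemisphere, x$measure, x$timepoint, sep = ".")
}

#' Write a results table to CSV
#'
#' Serialises a [run_analysis()] results table in the published block layout:
#' a `statistic` column followed by one column per (region, hemisphere,
#' measure, timepoint) block. The file re-loads bit-exactly with
#' [read_results_table()] at the default precision.
#'
#' @param results A `results_table`.
#' @param path Output path.
#' @param digits Significant digits for numeric fields (default 17, exact
#'   for doubles).
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(results, path, digits = 17L) {
  stopifnot(inherits(results, "results_table"))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) {
                    stop_imprint(sprintf("cannot write '%s': %s", path,
                                         conditionMessage(e)), "io_error")
                  })
  on.exit(close(con))
  labels <- if (nrow(results) > 0L) {
    vapply(seq_len(nrow(results)),
           function(i) results_block_label(results[i, ]), character(1L))
  } else character(0)
  fields <- c(RESULT_KEY_COLS, RESULT_NUMERIC_COLS, RESULT_LOGICAL_COLS,
              RESULT_CHAR_COLS)
  esc <- function(v) {
    v <- ifelse(is.na(v), "NA", v)
    needs <- grepl("[\",\n]", v)
    v[needs] <- paste0('"', gsub('"', '""', v[needs]), '"')
    v
  }
  writeLines(paste(c("statistic", esc(labels)), collapse = ","), con)
  for (f in fields) {
    v <- results[[f]]
    cells <- if (f %in% RESULT_NUMERIC_COLS) {
      fmt_num(v, digits)
    } else {
      as.character(v)
    }
    writeLines(paste(c(f, esc(cells)), collapse = ","), con)
  }
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path Path to a block-layout results CSV.
#' @return A `results_table` data frame (one row per block).
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) {
    stop_imprint(sprintf("file '%s' does not exist", path), "io_error")
  }
  raw <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (names(raw)[1L] != "statistic") {
    stop_imprint("not a results-table file (missing 'statistic' column)",
                 "schema_error")
  }
  n_blocks <- ncol(raw) - 1L
  fields <- raw$statistic
  out <- empty_results_row()[rep(1L, max(n_blocks, 1L)), , drop = FALSE]
  out <- out[seq_len(n_blocks), , drop = FALSE]
  rownames(out) <- NULL
  for (i in seq_along(fields)) {
    f <- fields[i]
    if (!f %in% names(out)) next
    vals <- as.character(raw[i, -1L])
    out[[f]] <- if (f %in% RESULT_NUMERIC_COLS) {
      suppressWarnings(as.numeric(vals))
    } else if (f %in% RESULT_LOGICAL_COLS) {
      as.logical(vals)
    } else {
      vals[!is.na(vals) & vals == "NA"] <- NA_character_
      as.character(vals)
    }
  }
  class(out) <- c("results_table", "data.frame")
  out
}
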