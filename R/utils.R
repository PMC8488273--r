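# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Classed errors so callers and tests can distinguish failure modes.
stop_imprint <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "imprintstat_error")))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_imprint(sprintf("'%s' must be a single finite number", name),
                 "invalid_argument")
  }
  if (x < lower || x > upper) {
    stop_imprint(sprintf("'%s' must be in [%s, %s], got %s",
                         name, lower, upper, format(x)),
                 "invalid_argument")
  }
  invisible(x)
}

# First line of a delimited file decides "," vs tab when not given explicitly.
detect_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (length(line) == 0L) {
    stop_imprint(sprintf("file '%s' is empty", path), "schema_error")
  }
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

read_table_file <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    stop_imprint(sprintf("file '%s' does not exist", path), "io_error")
  }
  delim <- delim %||% detect_delim(path)
  utils::read.table(path, header = TRUE, sep = delim, dec = ".",
                    stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE, fileEncoding = "UTF-8")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_imprint(sprintf("%s is missing required column(s): %s",
                         what, paste(missing, collapse = ", ")),
                 "schema_error")
  }
  invisible(df)
}

# Strict numeric coercion that reports the offending row, not just NA.
parse_numeric <- function(x, column, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)) &
                 toupper(trimws(x)) != "NA")
  if (length(bad) > 0L) {
    stop_imprint(sprintf("%s: non-numeric value '%s' in column '%s' (row %d)",
                         what, x[bad[1L]], column, bad[1L]),
                 "parse_error")
  }
  out
}

parse_logical <- function(x, column, what) {
  z <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(z))
  out[z %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[z %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    stop_imprint(sprintf("%s: value '%s' in column '%s' (row %d) is not a flag",
                         what, x[bad[1L]], column, bad[1L]),
                 "parse_error")
  }
  as.logical(out)
}

fmt_num <- function(x, digits = 17L) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}
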