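# Standard-curve calibration of immunoblot optical densities.
#
# Each autoradiograph carries four standards (15, 30, 45, 60 ug total
# protein). Band optical density is linear in loaded protein over this range,
# so an ordinary least-squares line of OD on micrograms defines, per gel, the
# OD corresponding to 30 ug. Dividing a sample band's OD by that value gives
# the "relative amount of protein": 1.0 is the signal of a 30 ug standard
# load on the same gel, which makes measurements comparable across gels with
# different film exposures and antibody gains.

DEFAULT_STANDARDS <- c(15, 30, 45, 60)

#' Fit a per-gel standard-curve calibration
#'
#' Ordinary least-squares line of optical density on micrograms of total
#' protein across the calibration standards of one autoradiograph. The line's
#' value at 30 micrograms defines one unit of relative protein amount.
#'
#' @param micrograms Standard protein amounts (ug, > 0); at least two distinct
#'   values, unique within a gel.
#' @param od Optical densities of the standard bands (>= 0), same length.
#' @param gel_id Identifier of the gel/autoradiograph.
#' @param through_origin If `TRUE`, force the line through the origin
#'   (no intercept). Default `FALSE`: the intercept is estimated.
#' @return An object of class `gel_calibration`: list with `gel_id`, `slope`
#'   (OD per ug), `intercept` (OD), `od_at_30`, `r_squared`, `n`,
#'   `through_origin` and the standards as `points`.
#' @details `od_at_30` is evaluated from the fitted line, not read off the raw
#'   30 ug band, so calibration does not hinge on a single standard.
#'   `r_squared` is 1 - RSS/TSS about the mean OD, clamped to \[0, 1\]; a flat
#'   set of ODs (zero OD variance) gives slope 0 and `r_squared` 0.
#' @export
fit_calibration <- function(micrograms, od, gel_id = "gel",
                            through_origin = FALSE) {
  micrograms <- as.numeric(micrograms)
  od <- as.numeric(od)
  if (length(micrograms) != length(od)) {
    stop_imprint("micrograms and od must have equal length", "invalid_argument")
  }
  keep <- !is.na(micrograms) & !is.na(od)
  micrograms <- micrograms[keep]
  od <- od[keep]
  if (any(micrograms <= 0)) {
    stop_imprint("standard amounts must be positive", "invalid_argument")
  }
  if (any(od < 0)) {
    stop_imprint("optical densities must be nonnegative", "invalid_argument")
  }
  if (anyDuplicated(micrograms)) {
    stop_imprint(sprintf("gel '%s': duplicated standard amounts", gel_id),
                 "duplicate_standards")
  }
  if (length(unique(micrograms)) < 2L) {
    stop_imprint(sprintf(
      "gel '%s': at least 2 distinct standard amounts are required", gel_id),
      "insufficient_standards")
  }
  if (through_origin) {
    fit <- stats::lm(od ~ 0 + micrograms)
    slope <- unname(stats::coef(fit)[1L])
    intercept <- 0
  } else {
    fit <- stats::lm(od ~ micrograms)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
  }
  tss <- sum((od - mean(od))^2)
  rss <- sum(stats::resid(fit)^2)
  r2 <- if (tss == 0) 0 else min(max(1 - rss / tss, 0), 1)
  od30 <- intercept + 30 * slope
  if (od30 <= 0) {
    stop_imprint(sprintf(
      "gel '%s': degenerate calibration, fitted OD at 30 ug is %.4g <= 0",
      gel_id, od30), "degenerate_calibration")
  }
  structure(list(
    gel_id = gel_id,
    slope = slope,
    intercept = intercept,
    od_at_30 = od30,
    r_squared = r2,
    n = length(od),
    through_origin = through_origin,
    points = data.frame(micrograms = micrograms, od = od)
  ), class = "gel_calibration")
}

#' @export
print.gel_calibration <- function(x, ...) {
  cat(sprintf(
    "Gel '%s' calibration: OD = %.4g + %.4g * ug (OD at 30 ug = %.4g, r^2 = %.4f, n = %d)\n",
    x$gel_id, x$intercept, x$slope, x$od_at_30, x$r_squared, x$n))
  invisible(x)
}

#' Relative amount of protein
#'
#' Divides a band's optical density by the calibration line's OD at 30
#' micrograms on the same gel, giving the relative amount of protein
#' (1.0 = the 30 ug standard signal).
#'
#' @param od Optical density (>= 0). Vectorised.
#' @param cal A [fit_calibration()] result for the band's gel.
#' @return Numeric vector of relative amounts.
#' @export
relative_amount <- function(od, cal) {
  if (!inherits(cal, "gel_calibration")) {
    stop_imprint("'cal' must be a gel_calibration", "invalid_argument")
  }
  od <- as.numeric(od)
  if (any(od < 0, na.rm = TRUE)) {
    stop_imprint("optical densities must be nonnegative", "invalid_argument")
  }
  od / cal$od_at_30
}

#' Linearity quality gate for a calibration
#'
#' Flags gels whose standards fit a straight line poorly; such gels should be
#' excluded from analysis.
#'
#' @param cal A [fit_calibration()] result.
#' @param threshold Minimum acceptable r-squared; default 0.95.
#' @return List with `pass`, `r_squared`, `threshold`, `gel_id`.
#' @export
calibration_linearity <- function(cal, threshold = 0.95) {
  if (!inherits(cal, "gel_calibration")) {
    stop_imprint("'cal' must be a gel_calibration", "invalid_argument")
  }
  assert_number(threshold, "threshold", 0, 1)
  list(pass = cal$r_squared >= threshold,
       r_squared = cal$r_squared,
       threshold = threshold,
       gel_id = cal$gel_id)
}

#' Calibrate sample optical densities against per-gel standards
#'
#' Fits one calibration per gel from a standards table, applies the linearity
#' gate, and converts sample ODs to relative amounts. Samples on failing gels
#' are dropped and reported.
#'
#' @param samples Data frame with columns `gel_id` and `od` plus any
#'   identifying columns (chick, region, ...), one row per band.
#' @param standards Data frame with columns `gel_id`, `micrograms`, `od`.
#' @param through_origin Passed to [fit_calibration()].
#' @param linearity_threshold Passed to [calibration_linearity()]; gels below
#'   it are excluded.
#' @return `samples` with an added `relative_amount` column (failing gels
#'   removed); attribute `"dropped_gels"` lists excluded gels with their
#'   r-squared, attribute `"calibrations"` the per-gel fits.
#' @export
apply_calibration <- function(samples, standards, through_origin = FALSE,
                              linearity_threshold = 0.95) {
  require_columns(samples, c("gel_id", "od"), "samples table")
  require_columns(standards, c("gel_id", "micrograms", "od"), "standards table")
  samples$od <- as.numeric(samples$od)
  gels <- unique(as.character(samples$gel_id))
  missing <- setdiff(gels, unique(as.character(standards$gel_id)))
  if (length(missing) > 0L) {
    stop_imprint(sprintf("no calibration standards for gel(s): %s",
                         paste(missing, collapse = ", ")),
                 "insufficient_standards")
  }
  cals <- lapply(gels, function(g) {
    st <- standards[as.character(standards$gel_id) == g, , drop = FALSE]
    fit_calibration(st$micrograms, st$od, gel_id = g,
                    through_origin = through_origin)
  })
  names(cals) <- gels
  qc <- vapply(cals, function(cal) {
    calibration_linearity(cal, linearity_threshold)$pass
  }, logical(1L))
  dropped <- data.frame(
    gel_id = gels[!qc],
    r_squared = vapply(cals[!qc], `[[`, numeric(1L), "r_squared")
  )
  if (nrow(dropped) > 0L) {
    message(sprintf("apply_calibration: excluding %d gel(s) failing linearity (r^2 < %g): %s",
                    nrow(dropped), linearity_threshold,
                    paste(dropped$gel_id, collapse = ", ")))
  }
  out <- samples[as.character(samples$gel_id) %in% gels[qc], , drop = FALSE]
  out$relative_amount <- vapply(seq_len(nrow(out)), function(i) {
    relative_amount(out$od[i], cals[[as.character(out$gel_id[i])]])
  }, numeric(1L))
  attr(out, "dropped_gels") <- dropped
  attr(out, "calibrations") <- cals
  out
}
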