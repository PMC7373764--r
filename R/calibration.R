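#' Linear spectrophotometric calibration
#'
#' A straight-line map between concentration (mg/L) and absorbance,
#' `A = slope * C + intercept`, as produced by a standard curve such as the
#' 4-aminoantipyrine phenol assay read at 500 nm, or an OD600 vs dry-biomass
#' regression. The stored direction is concentration -> absorbance; the
#' inverse is applied when reading unknowns.
#'
#' If the assay dilutes the sample before reading (e.g. 50 uL supernatant
#' made up to 1 mL is a 20-fold dilution), set `dilution` to the factor by
#' which reported concentrations must be multiplied; a standard curve built
#' on already-diluted samples uses the default of 1.
#'
#' @param slope Absorbance per (mg/L); must be > 0.
#' @param intercept Blank absorbance (dimensionless).
#' @param range Concentration interval `c(low, high)` (mg/L) over which the
#'   curve was calibrated. Readings inverting outside it trigger a warning
#'   (extrapolation), not an error. Default `c(0, 1200)`, the working range
#'   of a phenol standard series run from 100 to 1200 mg/L.
#' @param dilution Multiplicative dilution factor applied to inverted
#'   concentrations (default 1).
#' @return An object of class `linear_calibration`.
#' @examples
#' phenol_cal <- linear_calibration(slope = 0.002447, intercept = 0.1423)
#' absorbance_to_concentration(0.38697, phenol_cal)
#' @export
linear_calibration <- function(slope, intercept, range = c(0, 1200),
                               dilution = 1) {
  stop_if_not_number(slope, "slope", positive = TRUE)
  stop_if_not_number(intercept, "intercept")
  stop_if_not_number(dilution, "dilution", positive = TRUE)
  if (!is.numeric(range) || length(range) != 2L || any(is.na(range)) ||
      range[1] >= range[2] || range[1] < 0)
    stop("'range' must be c(low, high) with 0 <= low < high", call. = FALSE)
  structure(
    list(slope = slope, intercept = intercept,
         range = as.numeric(range), dilution = dilution),
    class = "linear_calibration"
  )
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf(
    "Linear calibration: A = %.6g * C + %.6g  (valid %g-%g mg/L, dilution x%g)\n",
    x$slope, x$intercept, x$range[1], x$range[2], x$dilution))
  invisible(x)
}

#' Invert an absorbance reading to a concentration
#'
#' Applies the inverse of the calibration line, `C = (A - intercept)/slope`,
#' then the dilution factor. Blank scatter is tolerated: readings below the
#' intercept by no more than `clamp_tol` (as a fraction of the intercept)
#' clamp to 0 mg/L; readings further below signal an error, since a negative
#' apparent concentration beyond blank noise indicates an invalid reading.
#' Concentrations outside the calibrated range are returned with an
#' extrapolation warning.
#'
#' @param a Absorbance reading(s).
#' @param cal A [linear_calibration()].
#' @param clamp_tol Fraction of the intercept treated as blank noise
#'   (default 0.02).
#' @return Concentration(s), mg/L.
#' @export
absorbance_to_concentration <- function(a, cal, clamp_tol = 0.02) {
  stopifnot(inherits(cal, "linear_calibration"))
  if (!is.numeric(a) || any(is.na(a)))
    stop("'a' must be numeric with no missing values", call. = FALSE)
  floor_a <- cal$intercept - clamp_tol * abs(cal$intercept)
  if (any(a < floor_a))
    stop(sprintf(
      "invalid reading: absorbance %.5g is more than %g%% below the blank intercept %.5g",
      min(a), 100 * clamp_tol, cal$intercept), call. = FALSE)
  conc <- (a - cal$intercept) / cal$slope * cal$dilution
  conc[a < cal$intercept] <- 0
  out_of_range <- conc > cal$range[2] | conc < cal$range[1]
  if (any(out_of_range))
    warning(sprintf(
      "%d reading(s) invert outside the calibrated range [%g, %g] mg/L (extrapolation)",
      sum(out_of_range), cal$range[1], cal$range[2]), call. = FALSE)
  conc
}

#' Forward-evaluate a calibration line
#'
#' Maps concentration to predicted absorbance, `A = slope * (C/dilution) +
#' intercept`. This is the forward model used by the synthetic-data
#' generator when emitting raw instrument readings; it is the exact inverse
#' of [absorbance_to_concentration()] over the valid range.
#'
#' @param x Concentration(s), mg/L; must be non-negative.
#' @inheritParams absorbance_to_concentration
#' @return Absorbance value(s).
#' @export
concentration_to_absorbance <- function(x, cal) {
  stopifnot(inherits(cal, "linear_calibration"))
  if (!is.numeric(x) || any(is.na(x)))
    stop("'x' must be numeric with no missing values", call. = FALSE)
  if (any(x < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  cal$slope * (x / cal$dilution) + cal$intercept
}

#' Convert OD600 readings to dry biomass
#'
#' Applies the inverse of a user-supplied OD600 vs dry-biomass regression
#' elementwise to a series of optical-density readings. No default
#' coefficient exists: the OD-to-dry-weight relationship is strain- and
#' instrument-specific and must be calibrated per study, so a missing
#' calibration is a configuration error, caught before any kinetics run.
#'
#' @param od OD600 reading(s).
#' @param coeff A [linear_calibration()] mapping dry biomass (mg/L) to
#'   OD600.
#' @return Dry biomass, mg/L.
#' @export
od_to_dry_biomass <- function(od, coeff) {
  if (missing(coeff) || is.null(coeff))
    stop(paste(
      "no OD600 -> dry-biomass calibration supplied:",
      "provide a linear_calibration() (config key 'biomass') fitted from",
      "growth absorbance vs dry-weight standards"), call. = FALSE)
  stopifnot(inherits(coeff, "linear_calibration"))
  absorbance_to_concentration(od, coeff)
}
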