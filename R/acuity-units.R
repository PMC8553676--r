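#' Convert between decimal acuity and logMAR
#'
#' Visual acuity is expressed interchangeably as decimal acuity (Snellen
#' fraction) or as logMAR, the logarithm of the minimum angle of resolution:
#' `logmar = -log10(decimal)`.
#'
#' @param decimal decimal acuity, > 0
#' @param logmar logMAR value
#' @return the converted acuity value
#' @examples
#' logmar_to_decimal(0)     # 1.0
#' decimal_to_logmar(1.6)   # about -0.2
#' @export
decimal_to_logmar <- function(decimal) {
  stopifnot(is.numeric(decimal), all(decimal > 0))
  -log10(decimal)
}

#' @rdname decimal_to_logmar
#' @export
logmar_to_decimal <- function(logmar) {
  stopifnot(is.numeric(logmar), all(is.finite(logmar)))
  10^(-logmar)
}

#' Dominant spatial frequency of a checkerboard stimulus
#'
#' One spatial cycle spans two checks along the check edge, so a check of
#' `c` arcmin has a dominant spatial frequency of `60 / (2 c)` cycles per
#' degree.  The `"diagonal"` convention multiplies by `sqrt(2)` to refer to
#' the fundamental along the checkerboard diagonal; the choice is absorbed
#' by the acuity conversion factor downstream, so the default edge
#' convention is used throughout unless requested otherwise.
#'
#' @param check_size check edge length in arcmin, > 0
#' @param convention `"edge"` (default) or `"diagonal"`
#' @return spatial frequency in cycles/degree
#' @export
check_size_to_sf <- function(check_size, convention = c("edge", "diagonal")) {
  stopifnot(is.numeric(check_size), all(check_size > 0))
  convention <- match.arg(convention)
  sf <- 60 / (2 * check_size)
  if (convention == "diagonal") sf <- sf * sqrt(2)
  sf
}

#' Spatial-frequency limit implied by a logMAR acuity
#'
#' Inverse of the acuity conversion used by [to_acuity()]:
#' `sf_limit = 10^(-logmar) / conversion_factor`.  Used by the synthetic
#' generator to plant a ground-truth tuning-curve cutoff.
#'
#' @param logmar acuity in logMAR
#' @param conversion_factor decimal acuity per cycle/degree, > 0
#' @return spatial frequency limit in cycles/degree
#' @export
logmar_to_sf_limit <- function(logmar, conversion_factor) {
  stopifnot(is.numeric(logmar), all(is.finite(logmar)),
            is.numeric(conversion_factor), conversion_factor > 0)
  10^(-logmar) / conversion_factor
}

#' Default decimal-acuity-per-cpd conversion factor
#'
#' A single calibration constant maps the extrapolated spatial-frequency
#' limit to decimal acuity.  The default, 1/17.6 decimal acuity per
#' cycle/degree, is a placeholder calibration (decimal acuity 1.0 at
#' 17.6 cpd); clinical use requires a locally calibrated value, which is
#' why [to_acuity()] takes the factor as an explicit argument with no
#' default.
#'
#' @return the default conversion factor (decimal acuity per cpd)
#' @export
default_conversion_factor <- function() 1 / 17.6
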