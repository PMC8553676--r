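#' Define a pattern-reversal stimulus set
#'
#' A steady-state acuity run presents checkerboards of six check sizes,
#' each reversing at a fixed rate, and records the EEG in short segments.
#' The first harmonic of the response sits at the reversal rate, so the
#' segment length must contain a whole number of response cycles for the
#' harmonic to fall exactly on a DFT bin; the constructor enforces this.
#'
#' Defaults: six check sizes in a geometric series with factor 2
#' (40 ... 1.25 arcmin, spanning 1.5 log10 units of spatial frequency),
#' 8 reversals/s, 1-s segments, 80 segments per recording, 1000 Hz
#' sampling.
#'
#' @param check_sizes six check sizes in arcmin, strictly decreasing
#' @param reversal_rate pattern reversals per second
#' @param segment_length segment duration in seconds
#' @param n_segments number of segments per recording
#' @param sampling_rate sampling rate in Hz
#' @param sf_convention spatial-frequency convention, see [check_size_to_sf()]
#' @return an object of class `vep_stimulus`
#' @examples
#' stim <- stimulus_set()
#' stim$spatial_frequencies
#' @export
stimulus_set <- function(check_sizes = c(40, 20, 10, 5, 2.5, 1.25),
                         reversal_rate = 8,
                         segment_length = 1,
                         n_segments = 80,
                         sampling_rate = 1000,
                         sf_convention = c("edge", "diagonal")) {
  sf_convention <- match.arg(sf_convention)
  stopifnot(is.numeric(check_sizes), all(check_sizes > 0),
            reversal_rate > 0, segment_length > 0,
            n_segments >= 1, sampling_rate > 0)
  if (length(check_sizes) != 6L)
    stop("`check_sizes` must contain exactly 6 check sizes, got ",
         length(check_sizes))
  if (any(diff(check_sizes) >= 0))
    stop("`check_sizes` must be strictly decreasing in arcmin ",
         "(increasing spatial frequency)")
  n_samp <- segment_length * sampling_rate
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("segment_length x sampling_rate must be an integer number of samples")
  n_cyc <- reversal_rate * segment_length
  if (abs(n_cyc - round(n_cyc)) > 1e-9)
    stop("reversal_rate x segment_length must be a whole number of cycles ",
         "per segment so the first harmonic falls on a DFT bin")
  structure(list(
    check_sizes = check_sizes,
    spatial_frequencies = check_size_to_sf(check_sizes, sf_convention),
    reversal_rate = reversal_rate,
    segment_length = segment_length,
    n_segments = n_segments,
    sampling_rate = sampling_rate,
    sf_convention = sf_convention,
    samples_per_segment = as.integer(round(n_samp))
  ), class = "vep_stimulus")
}

#' @export
print.vep_stimulus <- function(x, ...) {
  cat("Pattern-reversal stimulus set\n")
  cat("  check sizes (arcmin):", paste(signif(x$check_sizes, 4), collapse = ", "), "\n")
  cat("  spatial freq (cpd):  ", paste(signif(x$spatial_frequencies, 4), collapse = ", "), "\n")
  cat(sprintf("  %g reversals/s, %g-s segments x %d, %g Hz sampling\n",
              x$reversal_rate, x$segment_length, x$n_segments, x$sampling_rate))
  invisible(x)
}
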