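#' Split a recording into segments and reject blink artifacts
#'
#' Segments whose peak amplitude (maximum absolute deviation from
#' baseline, the default criterion) exceeds the rejection threshold are
#' discarded; this operationalizes the classic 120-uV blink-rejection
#' criterion.  A peak-to-peak criterion is available as an alternative.
#'
#' @param recording a `vep_recording` (or any list with `samples`,
#'   `sampling_rate` and `segment_length`)
#' @param threshold rejection threshold in uV; a segment is rejected iff
#'   its criterion value exceeds (strictly) this threshold
#' @param criterion `"peak"` (max |amplitude|, default) or
#'   `"peak_to_peak"` (max - min)
#' @return a list with `segments` (samples x kept-segments matrix, in
#'   temporal order), `kept` (indices), `n_kept`, `n_rejected`.  If every
#'   segment is rejected, `n_kept` is 0 and `segments` has zero columns
#'   ("no usable data", not an error); downstream analysis propagates this
#'   as a missing spectral response.
#' @export
segment_and_reject <- function(recording, threshold = 120,
                               criterion = c("peak", "peak_to_peak")) {
  criterion <- match.arg(criterion)
  stopifnot(threshold > 0)
  n_samp <- round(recording$segment_length * recording$sampling_rate)
  n <- length(recording$samples)
  if (n < n_samp) stop("recording shorter than one segment")
  if (n %% n_samp != 0)
    stop("recording length is not a whole number of segments")
  m <- matrix(recording$samples, nrow = n_samp)
  val <- switch(criterion,
                peak = apply(abs(m), 2, max),
                peak_to_peak = apply(m, 2, max) - apply(m, 2, min))
  kept <- which(val <= threshold)
  list(segments = m[, kept, drop = FALSE],
       kept = kept,
       n_kept = length(kept),
       n_rejected = ncol(m) - length(kept))
}

#' First-harmonic Fourier response of a set of segments
#'
#' Segments are averaged coherently in the time domain and the DFT bin at
#' the stimulation's first harmonic (the reversal rate) is read out.
#' Amplitudes are reported as single-sided sinusoid amplitudes in uV
#' (`2 |X_k| / N`).  The alternative `"spectral"` route averages the
#' per-segment amplitude spectra instead (incoherent averaging), which
#' does not cancel noise and is provided for comparison only.
#'
#' @param segments samples x segments matrix of accepted segments
#' @param reversal_rate first-harmonic frequency in Hz (reversals/s)
#' @param sampling_rate sampling rate in Hz
#' @param averaging `"coherent"` (default) or `"spectral"`
#' @return a list with `amplitude` (uV), `phase` (radians), `bin`
#'   (1-based index of the harmonic in `spectrum`), `spectrum`
#'   (single-sided amplitude spectrum up to Nyquist), `frequencies` (Hz)
#' @export
first_harmonic <- function(segments, reversal_rate, sampling_rate,
                           averaging = c("coherent", "spectral")) {
  averaging <- match.arg(averaging)
  stopifnot(is.matrix(segments), ncol(segments) >= 1)
  n <- nrow(segments)
  k <- reversal_rate * n / sampling_rate   # cycles per segment
  if (abs(k - round(k)) > 1e-9)
    stop("first harmonic (", reversal_rate, " Hz) does not fall on a DFT bin: ",
         "segments must contain a whole number of stimulation cycles")
  k <- as.integer(round(k))
  n_half <- floor(n / 2)
  if (k < 1 || k > n_half - 1)
    stop("harmonic bin outside the resolvable spectrum")
  if (averaging == "coherent") {
    avg <- rowMeans(segments)
    coefs <- stats::fft(avg)[seq_len(n_half + 1)] * 2 / n
    spectrum <- Mod(coefs)
    ph <- Arg(coefs[k + 1])
  } else {
    specs <- apply(segments, 2, function(s) {
      Mod(stats::fft(s)[seq_len(n_half + 1)]) * 2 / n
    })
    spectrum <- rowMeans(specs)
    avg <- rowMeans(segments)
    ph <- Arg(stats::fft(avg)[k + 1])
  }
  list(amplitude = spectrum[k + 1],
       phase = ph,
       bin = k + 1L,
       spectrum = spectrum,
       frequencies = (0:n_half) * sampling_rate / n)
}

#' Neighbour-bin noise estimate for a harmonic response
#'
#' Estimates the noise contribution at the harmonic bin as the square
#' root of the mean power of the `k_neighbors` nearest bins on each side
#' of the harmonic (2 k bins in total, the harmonic itself excluded).
#'
#' @param spectrum single-sided amplitude spectrum (uV per bin)
#' @param harmonic_bin 1-based index of the harmonic bin in `spectrum`
#' @param k_neighbors number of neighbour bins per side, >= 1
#' @return noise amplitude in uV
#' @export
estimate_noise <- function(spectrum, harmonic_bin, k_neighbors = 2) {
  stopifnot(k_neighbors >= 1)
  idx <- neighbor_bins(length(spectrum), harmonic_bin, k_neighbors)
  sqrt(mean(spectrum[idx]^2))
}

# indices of the k nearest bins on each side of the harmonic; errors when
# the spectrum is too short (DC bin and beyond-Nyquist bins excluded)
neighbor_bins <- function(n_bins, harmonic_bin, k_neighbors) {
  lo <- harmonic_bin - seq_len(k_neighbors)
  hi <- harmonic_bin + seq_len(k_neighbors)
  if (min(lo) < 2 || max(hi) > n_bins)
    stop("spectrum too short for ", k_neighbors,
         " neighbour bins on each side of the harmonic")
  c(rev(lo), hi)
}

#' Noise-correct a harmonic amplitude
#'
#' Power-domain subtraction floored at zero:
#' `sqrt(max(amplitude_raw^2 - noise_amplitude^2, 0))`.  Subtracting in
#' the power domain removes (in expectation) the upward Rayleigh bias
#' that additive noise imparts to the measured amplitude; the floor keeps
#' the reported amplitude non-negative.
#'
#' @param amplitude_raw measured harmonic amplitude, uV, >= 0
#' @param noise_amplitude neighbour-bin noise estimate, uV, >= 0
#' @return corrected amplitude in uV
#' @examples
#' noise_correct(5, 3)  # 4
#' noise_correct(2, 3)  # 0 (floored)
#' @export
noise_correct <- function(amplitude_raw, noise_amplitude) {
  stopifnot(all(amplitude_raw >= 0), all(noise_amplitude >= 0))
  sqrt(pmax(amplitude_raw^2 - noise_amplitude^2, 0))
}

#' Significance of a harmonic response against neighbour-bin noise
#'
#' Tests whether the harmonic amplitude exceeds the local noise floor
#' using an F-type power ratio: under a circularly symmetric Gaussian
#' null the harmonic power over the mean power of `m` neighbour bins is
#' F(2, 2m) distributed.  The p-value is the upper tail of that
#' distribution.
#'
#' Degenerate conventions: zero neighbour power with zero signal gives
#' p = 1; zero neighbour power with positive signal gives p = 0.
#'
#' @param amplitude_raw harmonic amplitude, uV
#' @param neighbor_amplitudes amplitudes of the >= 2 neighbour bins, uV
#' @return two-sided-equivalent upper-tail p-value in [0, 1]
#' @export
harmonic_significance <- function(amplitude_raw, neighbor_amplitudes) {
  m <- length(neighbor_amplitudes)
  if (m < 2) stop("need at least 2 neighbour bins")
  p_noise <- mean(neighbor_amplitudes^2)
  if (p_noise == 0) return(if (amplitude_raw > 0) 0 else 1)
  f <- amplitude_raw^2 / p_noise
  stats::pf(f, 2, 2 * m, lower.tail = FALSE)
}

#' Assemble a spectral response for one check size
#'
#' Combines a measured harmonic amplitude and its neighbour-bin context
#' into the per-check-size record used by tuning curves: noise estimate,
#' noise-corrected amplitude, signed corrected power and significance.
#'
#' @param spatial_frequency stimulus spatial frequency, cpd
#' @param amplitude_raw harmonic amplitude, uV
#' @param phase harmonic phase, radians
#' @param neighbor_amplitudes neighbour-bin amplitudes, uV
#' @param alpha single-test significance level
#' @param n_segments_kept,n_segments_rejected artifact-rejection counts
#' @param check_size originating check size, arcmin (optional metadata)
#' @return an object of class `spectral_response`; `status` is `"ok"`, or
#'   `"no_data"` when built via [analyze_recording()] from a recording
#'   with no usable segments
#' @export
spectral_response <- function(spatial_frequency, amplitude_raw, phase,
                              neighbor_amplitudes, alpha = 0.05,
                              n_segments_kept = NA_integer_,
                              n_segments_rejected = NA_integer_,
                              check_size = NA_real_) {
  stopifnot(spatial_frequency > 0, amplitude_raw >= 0)
  noise_amp <- sqrt(mean(neighbor_amplitudes^2))
  p <- harmonic_significance(amplitude_raw, neighbor_amplitudes)
  structure(list(
    spatial_frequency = spatial_frequency,
    log_sf = log10(spatial_frequency),
    amplitude_raw = amplitude_raw,
    phase = phase,
    noise_amplitude = noise_amp,
    amplitude_corrected = noise_correct(amplitude_raw, noise_amp),
    power_corrected = amplitude_raw^2 - noise_amp^2,
    p_value = p,
    significant = p < alpha,
    alpha = alpha,
    n_segments_kept = n_segments_kept,
    n_segments_rejected = n_segments_rejected,
    check_size = check_size,
    status = "ok"
  ), class = "spectral_response")
}

#' @export
print.spectral_response <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("Spectral response @ %.3g cpd: no usable data (%d segments rejected)\n",
                x$spatial_frequency, x$n_segments_rejected))
    return(invisible(x))
  }
  cat(sprintf(
    "Spectral response @ %.3g cpd: %.3g uV raw, %.3g uV noise, %.3g uV corrected, p = %.3g%s\n",
    x$spatial_frequency, x$amplitude_raw, x$noise_amplitude,
    x$amplitude_corrected, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Full spectral analysis of one recording
#'
#' Pipeline for a single check size: segment and reject artifacts
#' ([segment_and_reject()]), coherently average and extract the first
#' harmonic ([first_harmonic()]), estimate noise from neighbour bins
#' ([estimate_noise()]), correct the amplitude ([noise_correct()]) and
#' test significance ([harmonic_significance()]).
#'
#' @param recording a `vep_recording`
#' @param threshold artifact-rejection threshold, uV
#' @param k_neighbors neighbour bins per side for the noise estimate
#' @param alpha single-test significance level
#' @param averaging see [first_harmonic()]
#' @param criterion see [segment_and_reject()]
#' @return a `spectral_response`; when every segment is rejected the
#'   response has `status = "no_data"` and `NA` amplitudes
#' @export
analyze_recording <- function(recording, threshold = 120, k_neighbors = 2,
                              alpha = 0.05,
                              averaging = c("coherent", "spectral"),
                              criterion = c("peak", "peak_to_peak")) {
  averaging <- match.arg(averaging)
  criterion <- match.arg(criterion)
  seg <- segment_and_reject(recording, threshold, criterion)
  sf <- recording$spatial_frequency %||%
    check_size_to_sf(recording$check_size,
                     recording$sf_convention %||% "edge")
  if (seg$n_kept == 0) {
    return(structure(list(
      spatial_frequency = sf, log_sf = log10(sf),
      amplitude_raw = NA_real_, phase = NA_real_,
      noise_amplitude = NA_real_, amplitude_corrected = NA_real_,
      power_corrected = NA_real_, p_value = NA_real_,
      significant = FALSE, alpha = alpha,
      n_segments_kept = 0L, n_segments_rejected = seg$n_rejected,
      check_size = recording$check_size, status = "no_data"
    ), class = "spectral_response"))
  }
  fh <- first_harmonic(seg$segments, recording$reversal_rate,
                       recording$sampling_rate, averaging)
  nb <- neighbor_bins(length(fh$spectrum), fh$bin, k_neighbors)
  spectral_response(
    spatial_frequency = sf,
    amplitude_raw = fh$amplitude,
    phase = fh$phase,
    neighbor_amplitudes = fh$spectrum[nb],
    alpha = alpha,
    n_segments_kept = seg$n_kept,
    n_segments_rejected = seg$n_rejected,
    check_size = recording$check_size
  )
}
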