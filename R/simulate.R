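#' Tuning-curve amplitude of the simulated steady-state response
#'
#' The generator's response amplitude declines linearly in log10 spatial
#' frequency, from `peak_amplitude` at `decline_width` log-units below the
#' spatial-frequency limit down to exactly zero at the limit, and is zero
#' above it (flat at `peak_amplitude` further below the peak).  With the
#' default 2-log-unit decline the whole default stimulus range lies on the
#' descending limb for realistic acuities, so a straight-line extrapolation
#' of the sampled curve recovers the planted limit exactly.
#'
#' @param log_sf log10 spatial frequency (cpd) at which to evaluate
#' @param log_sf_limit log10 of the spatial-frequency limit
#' @param peak_amplitude amplitude at the tuning-curve peak, uV
#' @param decline_width width of the descending limb in log10 units
#' @return amplitude in uV (vectorized over `log_sf`)
#' @export
tuning_amplitude <- function(log_sf, log_sf_limit, peak_amplitude,
                             decline_width = 2) {
  stopifnot(peak_amplitude > 0, decline_width > 0)
  frac <- (log_sf_limit - log_sf) / decline_width
  peak_amplitude * pmin(pmax(frac, 0), 1)
}

# White noise with an optional 1/f (pink) admixture, total sd = sd.
# pink_weight is the fraction of noise *power* carried by the 1/f component.
make_eeg_noise <- function(n, sd, pink_weight = 0) {
  if (sd == 0) return(numeric(n))
  white <- stats::rnorm(n)
  if (pink_weight <= 0) return(sd * white)
  spec <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))            # avoid 1/0 at DC
  f <- pmin(f, n - f + 1)              # symmetric fold
  pink <- Re(stats::fft(spec / sqrt(f), inverse = TRUE))
  pink <- pink / stats::sd(pink)
  mix <- sqrt(1 - pink_weight) * white + sqrt(pink_weight) * pink
  sd * mix / stats::sd(mix)
}

#' Simulate one steady-state VEP recording
#'
#' Generates the raw single-channel time series for one check size of one
#' experimental condition: a sinusoid at the first harmonic of the
#' reversal rate whose amplitude follows [tuning_amplitude()] given the
#' condition's acuity, plus additive Gaussian noise and blink artifacts.
#' Blinks are 200-ms raised-cosine transients of 150-300 uV (deliberately
#' above the 120-uV rejection criterion), at most one per segment, with a
#' Poisson-distributed count at `blink_rate` per minute.
#'
#' @param participant a [participant_model()]
#' @param stimulus a [stimulus_set()]
#' @param check_size one of `stimulus$check_sizes`, arcmin
#' @param condition_logmar the condition's ground-truth logMAR; the
#'   spatial-frequency limit of the embedded tuning curve is
#'   `logmar_to_sf_limit(condition_logmar, conversion_factor)`
#' @param conversion_factor decimal acuity per cpd used to plant the limit
#' @param decline_width descending-limb width, log10 units
#' @param pink_weight fraction of noise power in an optional 1/f
#'   component (0 = pure white noise, the default)
#' @param seed RNG seed; defaults to the participant's seed.  `NULL`
#'   draws from the current RNG stream.
#' @return an object of class `vep_recording` with fields `samples` (uV),
#'   `sampling_rate`, `reversal_rate`, `check_size`, `segment_length`,
#'   `n_segments`, plus ground-truth metadata (`true_amplitude`,
#'   `blink_segments`, `condition_logmar`)
#' @export
simulate_recording <- function(participant, stimulus, check_size,
                               condition_logmar,
                               conversion_factor = default_conversion_factor(),
                               decline_width = 2,
                               pink_weight = 0,
                               seed = participant$seed) {
  stopifnot(inherits(participant, "vep_participant"),
            inherits(stimulus, "vep_stimulus"),
            is.finite(condition_logmar))
  if (!any(abs(check_size - stimulus$check_sizes) < 1e-9))
    stop("check_size ", check_size, " arcmin is not in the stimulus set (",
         paste(stimulus$check_sizes, collapse = ", "), ")")
  sf <- check_size_to_sf(check_size, stimulus$sf_convention)
  limit <- logmar_to_sf_limit(condition_logmar, conversion_factor)
  amp <- tuning_amplitude(log10(sf), log10(limit),
                          participant$peak_amplitude, decline_width)
  n_seg <- stimulus$n_segments
  n_samp <- stimulus$samples_per_segment
  fs <- stimulus$sampling_rate
  n_total <- n_seg * n_samp

  with_local_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    t <- (seq_len(n_total) - 1) / fs
    x <- amp * sin(2 * pi * stimulus$reversal_rate * t + phase)
    x <- x + make_eeg_noise(n_total, participant$noise_sd, pink_weight)

    blink_segments <- integer(0)
    total_min <- n_total / fs / 60
    n_blinks <- min(stats::rpois(1, participant$blink_rate * total_min), n_seg)
    if (n_blinks > 0) {
      blink_segments <- sort(sample.int(n_seg, n_blinks))
      blink_len <- round(0.2 * fs)
      shape <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = blink_len)))
      for (s in blink_segments) {
        start <- (s - 1) * n_samp +
          sample.int(max(n_samp - blink_len, 1), 1)
        idx <- start + seq_len(blink_len) - 1
        x[idx] <- x[idx] + stats::runif(1, 150, 300) * shape
      }
    }

    structure(list(
      samples = x,
      sampling_rate = fs,
      reversal_rate = stimulus$reversal_rate,
      check_size = check_size,
      segment_length = stimulus$segment_length,
      n_segments = n_seg,
      spatial_frequency = sf,
      sf_convention = stimulus$sf_convention,
      condition_logmar = condition_logmar,
      true_amplitude = amp,
      blink_segments = blink_segments
    ), class = "vep_recording")
  })
}

#' @export
print.vep_recording <- function(x, ...) {
  cat(sprintf(
    "VEP recording: check %g arcmin (%.3g cpd), %d x %g-s segments @ %g Hz\n",
    x$check_size, x$spatial_frequency, x$n_segments, x$segment_length,
    x$sampling_rate))
  cat(sprintf("  true first-harmonic amplitude %.3g uV, %d blink artifact(s)\n",
              x$true_amplitude, length(x$blink_segments)))
  invisible(x)
}

#' Simulate a tuning curve at the spectral-bin level
#'
#' Fast-path generator that samples the first-harmonic and neighbour-bin
#' amplitudes directly from their sampling distribution under the
#' time-domain model of [simulate_recording()] (white noise, no blinks):
#' the coherently averaged harmonic coefficient is the true amplitude plus
#' circular complex Gaussian noise with per-quadrature sd
#' `noise_sd * sqrt(2 / (samples_per_segment * n_segments))`, and
#' neighbour bins are noise-only draws from the same distribution.  The
#' resulting responses are statistically identical to running the full
#' time-domain pipeline, at a small fraction of the cost; used for large
#' training corpora and calibration sweeps.
#'
#' @inheritParams simulate_recording
#' @param k_neighbors noise-estimation bins per side, as in
#'   [estimate_noise()]
#' @param alpha single-test significance level
#' @return a `tuning_curve` (see [build_curve()])
#' @export
simulate_tuning_curve <- function(participant, stimulus, condition_logmar,
                                  conversion_factor = default_conversion_factor(),
                                  decline_width = 2,
                                  k_neighbors = 2,
                                  alpha = 0.05,
                                  seed = participant$seed) {
  stopifnot(inherits(participant, "vep_participant"),
            inherits(stimulus, "vep_stimulus"))
  limit <- logmar_to_sf_limit(condition_logmar, conversion_factor)
  sfs <- stimulus$spatial_frequencies
  amps <- tuning_amplitude(log10(sfs), log10(limit),
                           participant$peak_amplitude, decline_width)
  n_samp <- stimulus$samples_per_segment
  n_seg <- stimulus$n_segments
  sigma_q <- participant$noise_sd * sqrt(2 / (n_samp * n_seg))

  with_local_seed(seed, {
    responses <- lapply(seq_along(sfs), function(i) {
      phase <- stats::runif(1, 0, 2 * pi)
      coef <- amps[i] * exp(1i * phase) +
        complex(real = stats::rnorm(1, 0, sigma_q),
                imaginary = stats::rnorm(1, 0, sigma_q))
      nb <- Mod(complex(real = stats::rnorm(2 * k_neighbors, 0, sigma_q),
                        imaginary = stats::rnorm(2 * k_neighbors, 0, sigma_q)))
      spectral_response(
        spatial_frequency = sfs[i],
        amplitude_raw = Mod(coef),
        phase = Arg(coef),
        neighbor_amplitudes = nb,
        alpha = alpha,
        n_segments_kept = n_seg,
        n_segments_rejected = 0L,
        check_size = stimulus$check_sizes[i]
      )
    })
    build_curve(responses)
  })
}
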