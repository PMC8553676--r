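# shared fixtures and independent oracles

# a curve with fully controlled amplitudes/significance, via the tabular route
make_curve <- function(log_sf, amplitude, significant) {
  curve_from_table(data.frame(
    spatial_frequency = 10^log_sf,
    amplitude_corrected = amplitude,
    significant = significant))
}

# noise-free, blink-free participant at a given true logMAR
clean_participant <- function(logmar, seed = 1L, peak = 10) {
  participant_model(true_logmar_normal = logmar, peak_amplitude = peak,
                    noise_sd = 0, blink_rate = 0, seed = seed)
}

# full pipeline for one simulated condition: recordings -> curve
simulate_and_analyze <- function(participant, stimulus, logmar,
                                 seed_base = participant$seed, ...) {
  recs <- lapply(seq_along(stimulus$check_sizes), function(k) {
    simulate_recording(participant, stimulus, stimulus$check_sizes[k],
                       condition_logmar = logmar, seed = seed_base + k, ...)
  })
  build_curve(lapply(recs, analyze_recording))
}

# independent brute-force oracle for the paired sign-flip permutation test:
# plain double loop over all 2^n sign patterns, no shared code with the package
brute_force_perm_p <- function(d, stat_fun) {
  n <- length(d)
  obs <- abs(stat_fun(d))
  count <- 0
  for (i in 0:(2^n - 1)) {
    signs <- 1 - 2 * ((i %/% 2^(0:(n - 1))) %% 2)
    if (abs(stat_fun(signs * d)) >= obs) count <- count + 1
  }
  count / 2^n
}
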