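stim <- stimulus_set()

fake_recording <- function(samples, fs = 1000, f1 = 8, seg_len = 1) {
  structure(list(samples = samples, sampling_rate = fs, reversal_rate = f1,
                 check_size = 40, segment_length = seg_len,
                 n_segments = length(samples) / (fs * seg_len),
                 spatial_frequency = check_size_to_sf(40)),
            class = "vep_recording")
}

test_that("the 120-uV criterion rejects strictly above threshold", {
  seg <- rep(0, 1000)
  s121 <- seg; s121[500] <- -121
  s119 <- seg; s119[500] <- 119
  rec <- fake_recording(c(s121, s119, seg))
  out <- segment_and_reject(rec)
  expect_equal(out$kept, c(2L, 3L))
  expect_equal(out$n_rejected, 1L)
  # constant-zero recording: everything kept
  z <- segment_and_reject(fake_recording(rep(0, 4000)))
  expect_equal(z$n_kept, 4L)
  expect_equal(z$n_rejected, 0L)
})

test_that("all-rejected recordings yield a missing response, not an error", {
  rec <- fake_recording(rep(200, 3000))
  resp <- analyze_recording(rec)
  expect_equal(resp$status, "no_data")
  expect_equal(resp$n_segments_kept, 0L)
  expect_false(resp$significant)
  expect_true(is.na(resp$amplitude_raw))
})

test_that("a pure sinusoid returns its amplitude exactly, any segment count", {
  t <- (0:3999) / 1000
  for (A in c(1, 3.7)) {
    x <- A * sin(2 * pi * 8 * t + 0.4)
    fh <- first_harmonic(matrix(x, nrow = 1000), 8, 1000)
    expect_equal(fh$amplitude, A, tolerance = 1e-12)
  }
  # doubling the signal doubles the amplitude exactly (linearity)
  x <- sin(2 * pi * 8 * t)
  a1 <- first_harmonic(matrix(x, 1000), 8, 1000)$amplitude
  a2 <- first_harmonic(matrix(2 * x, 1000), 8, 1000)$amplitude
  expect_identical(a2, 2 * a1)
})

test_that("antiphase segments cancel under coherent averaging", {
  t <- (0:999) / 1000
  s <- sin(2 * pi * 8 * t)
  fh <- first_harmonic(cbind(s, -s), 8, 1000)
  expect_equal(fh$amplitude, 0, tolerance = 1e-12)
  # the incoherent (spectral) route does not cancel
  fh2 <- first_harmonic(cbind(s, -s), 8, 1000, averaging = "spectral")
  expect_equal(fh2$amplitude, 1, tolerance = 1e-12)
})

test_that("off-bin harmonics are rejected with the whole-cycles message", {
  expect_error(first_harmonic(matrix(rnorm(1000), 1000), 7.5, 1000),
               "whole number of stimulation cycles")
})

test_that("noisy amplitude estimates are unbiased within Monte-Carlo error", {
  # A = 2 uV + white noise sd 5 uV, 80 segments; SE estimated over 200 seeds
  t <- (0:79999) / 1000
  signal <- 2 * sin(2 * pi * 8 * t)
  amps <- vapply(1:200, function(i) {
    set.seed(i)
    x <- signal + rnorm(80000, 0, 5)
    first_harmonic(matrix(x, 1000), 8, 1000)$amplitude
  }, numeric(1))
  se <- sd(amps) / sqrt(length(amps))
  expect_lt(abs(mean(amps) - 2), 3 * se)
})

test_that("neighbour-bin noise estimation follows its definition", {
  spec <- rep(3, 50)
  expect_equal(estimate_noise(spec, 25), 3)
  spec2 <- rep(0, 50); spec2[25] <- 10
  expect_equal(estimate_noise(spec2, 25), 0)
  expect_error(estimate_noise(rep(1, 5), 2, k_neighbors = 2), "too short")
  # asymmetric power averages: sqrt(mean of the 2k bin powers)
  spec3 <- rep(0, 11); spec3[4:5] <- c(1, 2); spec3[7:8] <- c(3, 4)
  expect_equal(estimate_noise(spec3, 6), sqrt(mean(c(1, 4, 9, 16))))
})

test_that("noise-only noise estimate and harmonic amplitude share one RMS floor", {
  stim_small <- stimulus_set(n_segments = 10)
  p <- participant_model(true_logmar_normal = 3, noise_sd = 5, blink_rate = 0)
  m <- vapply(1:500, function(i) {
    rec <- simulate_recording(p, stim_small, 40, condition_logmar = 3, seed = i)
    r <- analyze_recording(rec)
    c(r$amplitude_raw, r$noise_amplitude)
  }, numeric(2))
  rms_harmonic <- sqrt(mean(m[1, ]^2))
  rms_noise <- sqrt(mean(m[2, ]^2))
  expect_lt(abs(rms_noise / rms_harmonic - 1), 0.05)
})

test_that("noise correction subtracts power, floored at zero", {
  expect_equal(noise_correct(5, 3), 4)
  expect_equal(noise_correct(3, 3), 0)
  expect_equal(noise_correct(2, 3), 0)
  expect_equal(noise_correct(0, 0), 0)
})

test_that("signed corrected power is unbiased under pure noise", {
  stim_small <- stimulus_set(n_segments = 10)
  p <- participant_model(true_logmar_normal = 3, noise_sd = 5, blink_rate = 0)
  m <- vapply(1:500, function(i) {
    rec <- simulate_recording(p, stim_small, 40, condition_logmar = 3,
                              seed = 5000 + i)
    r <- analyze_recording(rec)
    c(r$power_corrected, r$amplitude_raw^2)
  }, numeric(2))
  expect_lt(abs(mean(m[1, ])), 0.1 * mean(m[2, ]))
})

test_that("significance follows the F(2, 2m) ratio and its conventions", {
  # ratio 1 is unremarkable under the null
  expect_gt(harmonic_significance(1, rep(1, 4)), 0.4)
  # closed form: p = upper tail of F(2, 2m)
  expect_equal(harmonic_significance(2, c(1, 1, 1, 1)),
               pf(4, 2, 8, lower.tail = FALSE))
  # monotonically decreasing in signal power
  ps <- vapply(c(1, 2, 4, 8, 16), harmonic_significance,
               numeric(1), neighbor_amplitudes = rep(1, 4))
  expect_true(all(diff(ps) < 0))
  # degenerate conventions
  expect_equal(harmonic_significance(0, c(0, 0, 0, 0)), 1)
  expect_equal(harmonic_significance(1, c(0, 0, 0, 0)), 0)
  expect_error(harmonic_significance(1, 1), "at least 2")
})

test_that("the null type-I rate calibrates to alpha = 0.05", {
  # 10^4 noise-only responses via the spectral-bin fast path
  set.seed(77)
  p <- participant_model(true_logmar_normal = 3, noise_sd = 5, blink_rate = 0)
  sig <- replicate(1700, {
    cv <- simulate_tuning_curve(p, stimulus_set(), condition_logmar = 3,
                                seed = NULL)
    cv$points$significant
  })
  rate <- mean(sig)   # 1700 curves x 6 points > 10^4 null tests
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("re-analysis of the kept segments reproduces the pipeline (idempotence)", {
  p <- participant_model(noise_sd = 5, blink_rate = 10, seed = 4)
  rec <- simulate_recording(p, stim, 40, condition_logmar = 0)
  seg <- segment_and_reject(rec)
  expect_gt(seg$n_rejected, 0)
  direct <- analyze_recording(rec)
  # rebuild a recording from only the kept segments: same response
  rec2 <- fake_recording(as.vector(seg$segments))
  again <- analyze_recording(rec2)
  expect_equal(again$amplitude_raw, direct$amplitude_raw)
  expect_equal(again$p_value, direct$p_value)
  expect_equal(again$n_segments_rejected, 0L)
})
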