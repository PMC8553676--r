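stim <- stimulus_set()
cf <- default_conversion_factor()

make_response <- function(sf, amplitude, check_size = 60 / (2 * sf)) {
  spectral_response(spatial_frequency = sf, amplitude_raw = amplitude,
                    phase = 0, neighbor_amplitudes = rep(0, 4),
                    check_size = check_size)
}

test_that("curves are sorted ascending in log SF and reject duplicates", {
  resp <- lapply(c(10, 0.75, 3), make_response, amplitude = 5)
  cv <- build_curve(resp)
  expect_equal(cv$points$spatial_frequency, c(0.75, 3, 10))
  expect_true(all(diff(cv$points$log_sf) > 0))
  dup <- lapply(c(3, 3), make_response, amplitude = 5)
  expect_error(build_curve(dup), "duplicate spatial frequency")
  expect_error(build_curve(resp[1]), "at least 2")
})

test_that("noise-free curves reproduce the generator's tuning function exactly", {
  p <- clean_participant(logmar = 0.25, seed = 5)
  cv <- simulate_and_analyze(p, stim, 0.25)
  limit <- logmar_to_sf_limit(0.25, cf)
  expected <- tuning_amplitude(cv$points$log_sf, log10(limit), p$peak_amplitude)
  expect_equal(cv$points$amplitude_raw, expected, tolerance = 1e-10)
  expect_equal(cv$points$amplitude_corrected, expected, tolerance = 1e-10)
})

test_that("spurious-significance overrides follow the isolation rule", {
  amps <- c(6, 5, 1, 1, 2)
  cv1 <- make_curve(seq(0, 1.2, 0.3), amps, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(flag_spurious(cv1, "auto")$overrides, 5L)
  cv2 <- make_curve(seq(0, 1.2, 0.3), amps, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_length(flag_spurious(cv2, "auto")$overrides, 0)
  # one-gap points join the block and shield later ones only if close enough
  cv3 <- make_curve(seq(0, 1.5, 0.3), c(6, 1, 5, 1, 1, 2),
                    c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(flag_spurious(cv3, "auto")$overrides, 6L)
  # manual override wins regardless of p-value
  cv4 <- flag_spurious(cv1, "manual", indices = 4)
  expect_false(effective_significance(cv4)[4])
  expect_error(flag_spurious(cv1, "manual", indices = 9), "out of range")
})

test_that("a two-point descending line extrapolates to its abscissa intercept", {
  cv <- make_curve(c(0.5, 1.0), c(4, 2), c(TRUE, TRUE))
  fit <- fit_sf_limit(cv)
  expect_equal(fit$status, "ok")
  expect_equal(fit$intercept_log_sf, 1.5)
  expect_equal(fit$sf_limit, 10^1.5)
  expect_equal(fit$slope, -4)
})

test_that("the heuristic declines to estimate when it has no basis", {
  cv <- make_curve(c(0.5, 1.0), c(1, 1), c(FALSE, FALSE))
  expect_equal(fit_sf_limit(cv)$status, "no_estimate")
  # non-negative slope across the fit set
  cv2 <- make_curve(c(0.2, 0.6, 1.0), c(3, 2, 3), c(TRUE, TRUE, TRUE))
  fit2 <- fit_sf_limit(cv2)
  expect_equal(fit2$status, "no_estimate")
  expect_match(fit2$reason, "slope")
  # a single significant point leaves fewer than 2 fit points
  cv3 <- make_curve(c(0.2, 0.6), c(3, 0), c(TRUE, FALSE))
  expect_equal(fit_sf_limit(cv3)$status, "no_estimate")
  est <- estimate_acuity(cv, cf)
  expect_equal(est$status, "no_estimate")
  expect_true(is.na(est$logmar) && is.na(est$sf_limit))
})

test_that("noise-free extrapolation recovers 100 random planted limits", {
  set.seed(31)
  true_lm <- runif(100, -0.2, 0.8)
  errs <- vapply(seq_along(true_lm), function(i) {
    p <- clean_participant(true_lm[i], seed = 400 + i)
    cv <- simulate_tuning_curve(p, stim, condition_logmar = true_lm[i],
                                seed = NULL)
    fit <- fit_sf_limit(cv)
    expect_equal(fit$status, "ok")
    log10(fit$sf_limit) - log10(logmar_to_sf_limit(true_lm[i], cf))
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.02)
})

test_that("acuity conversion applies the factor, the clip and the logMAR identity", {
  # pre-clip decimal 2.0 -> reported 1.6, logMAR -log10(1.6)
  a <- to_acuity(2.0 / cf, cf)
  expect_true(a$clipped)
  expect_equal(a$decimal_acuity, 1.6)
  expect_equal(a$logmar, -log10(1.6))
  expect_equal(round(a$logmar, 1), -0.2)
  b <- to_acuity(1.0 / cf, cf)
  expect_false(b$clipped)
  expect_equal(b$logmar, 0)
  expect_equal(to_acuity(0.09 / cf, cf)$logmar, -log10(0.09))
  expect_error(to_acuity(-1, cf), "must be > 0")
  # round trip holds for every emitted estimate
  cv <- make_curve(c(0.5, 1.0), c(4, 2), c(TRUE, TRUE))
  est <- estimate_acuity(cv, cf)
  expect_equal(est$decimal_acuity, 10^(-est$logmar))
})

test_that("sf_limit is invariant under a common amplitude rescaling", {
  set.seed(61)
  base_curves <- lapply(1:20, function(i) {
    p <- participant_model(true_logmar_normal = runif(1, -0.1, 0.6),
                           noise_sd = 5, blink_rate = 0)
    simulate_tuning_curve(p, stim, condition_logmar = p$true_logmar_normal,
                          seed = NULL)
  })
  rescale <- function(cv, k) {
    cv$points$amplitude_corrected <- cv$points$amplitude_corrected * k
    cv
  }
  for (cv in base_curves) {
    f0 <- fit_sf_limit(cv)
    if (f0$status != "ok") next
    for (k in c(0.25, 0.5, 2, 1024)) {   # dyadic factors: rescaling is exact
      expect_identical(fit_sf_limit(rescale(cv, k))$sf_limit, f0$sf_limit)
    }
    for (k in c(3, 10, 1e-3, 7.3)) {     # arbitrary factors: exact to rounding
      expect_equal(fit_sf_limit(rescale(cv, k))$sf_limit, f0$sf_limit,
                   tolerance = 1e-12)
    }
  }
})

test_that("rescaling all spatial frequencies shifts the limit equivariantly", {
  cv <- make_curve(c(0.3, 0.6, 0.9, 1.2), c(8, 6, 4, 2),
                   c(TRUE, TRUE, TRUE, TRUE))
  f0 <- fit_sf_limit(cv)
  for (c_mult in c(0.5, 2, 3.7)) {
    cv2 <- cv
    cv2$points$spatial_frequency <- cv$points$spatial_frequency * c_mult
    cv2$points$log_sf <- log10(cv2$points$spatial_frequency)
    f2 <- fit_sf_limit(cv2)
    expect_equal(f2$sf_limit, f0$sf_limit * c_mult, tolerance = 1e-9)
  }
})

test_that("overriding the top significant point cannot meaningfully raise the limit", {
  # exact non-increase without noise
  p <- clean_participant(0.3, seed = 8)
  cv <- simulate_tuning_curve(p, stim, condition_logmar = 0.3, seed = NULL)
  f0 <- fit_sf_limit(cv)
  top <- max(which(effective_significance(cv)))
  f1 <- fit_sf_limit(flag_spurious(cv, "manual", indices = top))
  expect_lte(f1$sf_limit, f0$sf_limit * (1 + 1e-12))
  # with noise, any increase stays within the fit-resolution tolerance
  set.seed(91)
  for (i in 1:60) {
    pn <- participant_model(true_logmar_normal = runif(1, -0.1, 0.7),
                            noise_sd = 5, blink_rate = 0)
    cvn <- flag_spurious(simulate_tuning_curve(
      pn, stim, condition_logmar = pn$true_logmar_normal, seed = NULL), "auto")
    fn <- fit_sf_limit(cvn)
    sig <- effective_significance(cvn)
    if (fn$status != "ok" || sum(sig) < 2) next
    fo <- fit_sf_limit(flag_spurious(cvn, "manual", indices = max(which(sig))))
    if (fo$status == "ok")
      expect_lte(log10(fo$sf_limit), log10(fn$sf_limit) + 0.02)
  }
})

test_that("curves survive a round trip through their tabular form", {
  p <- participant_model(noise_sd = 5, blink_rate = 0, seed = 3)
  cv <- simulate_tuning_curve(p, stim, condition_logmar = 0.2)
  path <- tempfile(fileext = ".csv")
  write_responses(cv, path)
  cv2 <- curve_from_table(read.csv(path))
  expect_equal(fit_sf_limit(cv2)$sf_limit, fit_sf_limit(cv)$sf_limit)
})
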