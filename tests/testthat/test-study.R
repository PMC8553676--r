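# orchestration tests run on a reduced cohort (4 participants, 20 one-second
# segments) so the full pipeline stays fast while exercising every stage
small_config <- function(seed = 1, ...) {
  study_config(n_participants = 4, seed = seed,
               stimulus = stimulus_set(n_segments = 20),
               ml_corpus_n = 120, n_permutations = 2000, n_boot = 500, ...)
}

test_that("a full study run is deterministic and internally consistent", {
  res <- run_study(small_config(seed = 3))
  res2 <- run_study(small_config(seed = 3))
  keep <- c("ground_truth", "responses", "estimates", "comparisons", "log")
  expect_identical(res[keep], res2[keep])
  expect_equal(nrow(res$ground_truth), 4 * 4)
  expect_equal(nrow(res$comparisons), 3)
  # heuristic estimates exist and respect the logMAR/decimal identity
  h <- res$estimates[res$estimates$method == "heuristic" &
                       res$estimates$status == "ok", ]
  expect_gt(nrow(h), 0)
  expect_equal(h$decimal_acuity, 10^(-h$logmar))
  expect_true(all(h$logmar >= -log10(1.6) - 1e-12))
})

test_that("persisted intermediates reproduce the downstream estimates", {
  res <- run_study(small_config(seed = 6), output_dir = td <- tempfile())
  expect_true(all(file.exists(file.path(
    td, c("ground_truth.csv", "responses.csv", "estimates.csv",
          "comparisons.csv", "config.json", "run_log.txt")))))
  resp <- read.csv(file.path(td, "responses.csv"))
  est <- read.csv(file.path(td, "estimates.csv"))
  for (i in unique(resp$participant)) {
    for (cn in unique(resp$condition)) {
      pts <- resp[resp$participant == i & resp$condition == cn, ]
      cv <- curve_from_table(pts)
      cv$overrides <- which(pts[order(pts$log_sf), "overridden"])
      redo <- estimate_acuity(cv, res$config$conversion_factor)
      ref <- est[est$participant == i & est$condition == cn &
                   est$method == "heuristic", ]
      if (ref$status == "ok") {
        expect_equal(redo$logmar, ref$logmar, tolerance = 1e-9)
      } else {
        expect_equal(redo$status, "no_estimate")
      }
    }
  }
  unlink(td, recursive = TRUE)
})

test_that("recordings and cohorts survive a round trip through text files", {
  stim <- stimulus_set(n_segments = 5)
  p <- participant_model(noise_sd = 5, blink_rate = 5, seed = 12)
  rec <- simulate_recording(p, stim, 10, condition_logmar = 0.1)
  path <- tempfile(fileext = ".csv")
  write_recording(rec, path)
  rec2 <- read_recording(path)
  expect_equal(rec2$samples, rec$samples, tolerance = 1e-12)
  expect_equal(rec2$check_size, rec$check_size)
  expect_equal(analyze_recording(rec2)$p_value, analyze_recording(rec)$p_value,
               tolerance = 1e-9)
  co <- generate_cohort(n_participants = 2, seed = 2, stimulus = stim)
  d <- tempfile()
  write_cohort(co, d)
  expect_true(file.exists(file.path(d, "ground_truth.csv")))
  files <- list.files(d, pattern = "[.]csv$", recursive = TRUE)
  expect_length(files, 2 * 4 * 6 + 1)
  unlink(d, recursive = TRUE)
})

test_that("a planted occlusion effect is recovered with the right sign", {
  # low noise, modest cohorts: the recovered normal-vision mean difference
  # should carry the planted sign in >= 90% of runs
  hits <- vapply(1:10, function(s) {
    res <- run_study(study_config(
      n_participants = 8, effect = -0.06, noise_sd = 2, seed = 100 + s,
      stimulus = stimulus_set(n_segments = 20), ml = FALSE,
      n_permutations = 500, n_boot = 200))
    res$comparisons$mean_diff[res$comparisons$vision == "normal"] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null cohorts show no systematic occlusion effect", {
  ps <- vapply(1:8, function(s) {
    res <- run_study(study_config(
      n_participants = 6, effect = 0, noise_sd = 5, seed = 200 + s,
      stimulus = stimulus_set(n_segments = 20), ml = FALSE,
      n_permutations = 500, n_boot = 200))
    res$comparisons$p_mean[res$comparisons$vision == "normal"]
  }, numeric(1))
  # under the null, p-values should not pile up near zero
  expect_gt(mean(ps > 0.05), 0.5)
  expect_gt(min(ps), 0.001)
})

test_that("cohorts planted below the stimulus range yield no estimates", {
  stim <- stimulus_set()
  # true acuity below the lowest stimulus SF: logMAR beyond
  # -log10(conversion_factor * min SF) ~ 1.37 for the default set
  for (i in 1:5) {
    p <- clean_participant(1.6, seed = 70 + i)
    cv <- flag_spurious(simulate_tuning_curve(p, stim, condition_logmar = 1.6,
                                              seed = NULL), "auto")
    est <- estimate_acuity(cv, default_conversion_factor())
    expect_equal(est$status, "no_estimate")
  }
  # with realistic noise, chance significances can simulate a response at a
  # few check sizes (the multiple-testing problem), but no_estimate remains
  # the dominant outcome
  set.seed(55)
  st <- replicate(40, {
    p <- participant_model(true_logmar_normal = 1.6, noise_sd = 5,
                           blink_rate = 0)
    cv <- flag_spurious(simulate_tuning_curve(p, stim, condition_logmar = 1.6,
                                              seed = NULL), "auto")
    estimate_acuity(cv, default_conversion_factor())$status
  })
  expect_gt(mean(st == "no_estimate"), 0.5)
})
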