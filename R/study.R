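#' Configuration for a full synthetic study run
#'
#' Collects every tunable constant of the pipeline in one validated
#' object.  Analysis defaults are the standard clinical constants:
#' 120-uV artifact rejection, single-test alpha 0.05, decimal-acuity
#' clip ceiling 1.6, Bonferroni factor 2 for the two-vision-level family.
#'
#' @param n_participants cohort size
#' @param effect planted translucent-occlusion logMAR shift
#' @param noise_sd EEG noise sd, uV
#' @param blink_rate blink artifacts per minute
#' @param peak_amplitude median tuning-curve peak amplitude, uV
#' @param seed master RNG seed for the whole run
#' @param stimulus a [stimulus_set()]
#' @param threshold artifact-rejection threshold, uV
#' @param alpha single-test significance level
#' @param k_neighbors noise-estimation bins per side
#' @param conversion_factor decimal acuity per cpd
#' @param clip_ceiling maximum reportable decimal acuity
#' @param bonferroni_factor family size for the Bonferroni adjustment
#' @param n_permutations Monte-Carlo permutations (exhaustive enumeration
#'   is used automatically for n <= 20)
#' @param n_boot bootstrap replicates
#' @param auto_spurious apply the automatic spurious-significance
#'   override ([flag_spurious()] `"auto"`) before the heuristic
#' @param ml also run the neural-network estimator on the normal-vision
#'   conditions
#' @param ml_corpus_n training-corpus size for the network
#' @param ml_logmar_range logMAR range of the training corpus
#' @return an object of class `study_config`
#' @export
study_config <- function(n_participants = 16, effect = -0.06,
                         noise_sd = 5, blink_rate = 2, peak_amplitude = 10,
                         seed = 1L,
                         stimulus = stimulus_set(),
                         threshold = 120, alpha = 0.05, k_neighbors = 2,
                         conversion_factor = default_conversion_factor(),
                         clip_ceiling = 1.6, bonferroni_factor = 2,
                         n_permutations = 1e5, n_boot = 1999,
                         auto_spurious = TRUE,
                         ml = TRUE, ml_corpus_n = 300,
                         ml_logmar_range = c(-0.3, 0.5)) {
  stopifnot(n_participants >= 2, is.finite(effect), noise_sd >= 0,
            blink_rate >= 0, peak_amplitude > 0,
            inherits(stimulus, "vep_stimulus"),
            threshold > 0, alpha > 0, alpha < 1, k_neighbors >= 1,
            conversion_factor > 0, clip_ceiling > 0,
            bonferroni_factor >= 1, n_permutations >= 100, n_boot >= 100)
  structure(as.list(environment()), class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("Study config: n = %d, effect %+0.3f logMAR, noise %.1f uV, seed %d\n",
              x$n_participants, x$effect, x$noise_sd, x$seed))
  cat(sprintf("  threshold %g uV, alpha %g, clip %g, Bonferroni x%g, ML %s\n",
              x$threshold, x$alpha, x$clip_ceiling, x$bonferroni_factor,
              if (isTRUE(x$ml)) "on" else "off"))
  invisible(x)
}

# tuning curve for one condition of one cohort participant
cohort_curve <- function(cond, config) {
  if (inherits(cond$data, "tuning_curve")) return(cond$data)
  responses <- lapply(cond$data, analyze_recording,
                      threshold = config$threshold,
                      k_neighbors = config$k_neighbors,
                      alpha = config$alpha)
  build_curve(responses)
}

#' Spectral analysis and heuristic estimation over a whole cohort
#'
#' Runs the per-recording spectral pipeline and the heuristic acuity
#' algorithm for every participant and condition.
#'
#' @param cohort a [generate_cohort()] result
#' @param config a [study_config()]
#' @return a list with `responses` (one row per check size), `estimates`
#'   (one row per condition, method `"heuristic"`), `curves` (nested
#'   list, `curves[[participant]][[condition]]`)
#' @export
analyze_cohort <- function(cohort, config = study_config()) {
  stopifnot(inherits(cohort, "vep_cohort"))
  responses <- list(); estimates <- list(); curves <- list()
  for (i in seq_along(cohort$participants)) {
    part <- cohort$participants[[i]]
    curves[[i]] <- list()
    for (cn in names(part$conditions)) {
      cond <- part$conditions[[cn]]
      curve <- cohort_curve(cond, config)
      if (isTRUE(config$auto_spurious)) curve <- flag_spurious(curve, "auto")
      curves[[i]][[cn]] <- curve
      pts <- as.data.frame(curve)
      pts$participant <- i; pts$condition <- cn
      pts$vision <- cond$vision; pts$occlusion <- cond$occlusion
      responses[[length(responses) + 1]] <- pts
      est <- estimate_acuity(curve, config$conversion_factor,
                             config$clip_ceiling)
      estimates[[length(estimates) + 1]] <- data.frame(
        participant = i, condition = cn, vision = cond$vision,
        occlusion = cond$occlusion, method = "heuristic",
        status = est$status,
        sf_limit = est$sf_limit, decimal_acuity = est$decimal_acuity,
        logmar = est$logmar, clipped = est$clipped,
        n_fit_points = length(est$fit_points),
        true_logmar = cond$true_logmar)
    }
  }
  list(responses = do.call(rbind, responses),
       estimates = do.call(rbind, estimates),
       curves = curves)
}

#' Compare occlusion conditions within a vision level
#'
#' The study's inferential contrast: per participant, logMAR with
#' translucent minus opaque contralateral occlusion, tested with the
#' sign-flip permutation test (median and mean statistics) and
#' summarized with percentile bootstrap intervals; single-test p-values
#' are Bonferroni-adjusted for the two-vision-level family.
#'
#' @param estimates an estimates table (see [analyze_cohort()]) with one
#'   row per participant x condition for one method
#' @param vision `"normal"` or `"degraded"`
#' @param config a [study_config()] (statistics parameters)
#' @param seed RNG seed for resampling
#' @return one-row data frame: n pairs, exclusions, median/mean
#'   differences, permutation p-values (raw and Bonferroni-adjusted),
#'   bootstrap CIs
#' @export
compare_occlusion <- function(estimates, vision = c("normal", "degraded"),
                              config = study_config(), seed = NULL) {
  vision <- match.arg(vision)
  e <- estimates[estimates$vision == vision, ]
  wide <- merge(
    e[e$occlusion == "translucent", c("participant", "logmar")],
    e[e$occlusion == "opaque", c("participant", "logmar")],
    by = "participant", suffixes = c("_translucent", "_opaque"))
  pd <- paired_differences(wide$logmar_translucent, wide$logmar_opaque,
                           wide$participant)
  if (pd$n < 2)
    stop("fewer than 2 complete pairs in the ", vision, "-vision contrast")
  seeds <- with_local_seed(seed, draw_seeds(4))
  p_med <- permutation_test(pd, "median", config$n_permutations,
                            seed = seeds[1])
  p_mean <- permutation_test(pd, "mean", config$n_permutations,
                             seed = seeds[2])
  ci_med <- bootstrap_ci(pd, "median", n_boot = config$n_boot,
                         seed = seeds[3])
  ci_mean <- bootstrap_ci(pd, "mean", n_boot = config$n_boot,
                          seed = seeds[4])
  data.frame(
    vision = vision,
    n_pairs = pd$n, n_excluded = pd$n_missing,
    median_diff = stats::median(pd$diffs), mean_diff = mean(pd$diffs),
    p_median = p_med$p_value,
    p_median_bonferroni = bonferroni(p_med$p_value, config$bonferroni_factor),
    p_mean = p_mean$p_value,
    p_mean_bonferroni = bonferroni(p_mean$p_value, config$bonferroni_factor),
    ci_median_lower = ci_med$lower, ci_median_upper = ci_med$upper,
    ci_mean_lower = ci_mean$lower, ci_mean_upper = ci_mean$upper)
}

# polynomial rolling hash of a string, as 8 hex digits (config fingerprint)
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the complete synthetic study
#'
#' One-command replication of the full pipeline on synthetic data:
#' simulate the 2x2 cohort, run spectral analysis and the heuristic
#' estimator, train and apply the neural-network estimator
#' (normal-vision conditions only, as a network trained on the normal
#' acuity range refuses degraded-range curves), and compute the paired
#' occlusion contrasts at each vision level.
#'
#' @param config a [study_config()]
#' @param output_dir if non-`NULL`, persist every intermediate table
#'   there via [write_study_results()]
#' @return an object of class `study_results`: `config`, `ground_truth`,
#'   `responses`, `estimates` (heuristic and ml rows), `comparisons`,
#'   `ml_model`, `log`
#' @export
run_study <- function(config = study_config(), output_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  seeds <- with_local_seed(config$seed, draw_seeds(6))
  log <- c(sprintf("vepacuity %s | R %s",
                   as.character(utils::packageVersion("vepacuity")),
                   paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("master seed %d, config hash %s", config$seed,
                   config_hash(paste(deparse(config[setdiff(names(config), "stimulus")]),
                               collapse = ""))))

  cohort <- generate_cohort(
    n_participants = config$n_participants, effect = config$effect,
    stimulus = config$stimulus, seed = seeds[1],
    peak_amplitude = config$peak_amplitude, noise_sd = config$noise_sd,
    blink_rate = config$blink_rate,
    conversion_factor = config$conversion_factor)
  log <- c(log, sprintf("simulate: %d participants x 4 conditions x %d check sizes",
                        config$n_participants,
                        length(config$stimulus$check_sizes)))

  ana <- analyze_cohort(cohort, config)
  log <- c(log, sprintf("analyze: %d recordings, %d segments rejected in total",
                        nrow(ana$responses),
                        sum(ana$responses$n_segments_rejected)))
  estimates <- ana$estimates
  log <- c(log, sprintf("estimate (heuristic): %d/%d conditions with no estimate",
                        sum(estimates$status == "no_estimate"),
                        nrow(estimates)))

  ml_model <- NULL
  if (isTRUE(config$ml)) {
    corpus <- make_training_corpus(
      n = config$ml_corpus_n, logmar_range = config$ml_logmar_range,
      stimulus = config$stimulus, noise_sd = config$noise_sd,
      peak_amplitude = config$peak_amplitude,
      conversion_factor = config$conversion_factor, seed = seeds[2])
    ml_model <- train_acuity_model(corpus$curves, corpus$logmar,
                                   seed = seeds[3])
    ml_rows <- list()
    for (i in seq_along(ana$curves)) {
      for (cn in names(ana$curves[[i]])) {
        if (!startsWith(cn, "normal")) next
        pr <- predict(ml_model, ana$curves[[i]][[cn]])
        base <- estimates[estimates$participant == i &
                            estimates$condition == cn, ][1, ]
        ml_rows[[length(ml_rows) + 1]] <- data.frame(
          participant = i, condition = cn, vision = base$vision,
          occlusion = base$occlusion, method = "ml",
          status = if (pr$status == "ok") "ok" else "no_estimate",
          sf_limit = NA_real_,
          decimal_acuity = if (pr$status == "ok")
            logmar_to_decimal(pr$logmar) else NA_real_,
          logmar = pr$logmar, clipped = NA,
          n_fit_points = NA_integer_, true_logmar = base$true_logmar)
      }
    }
    ml_est <- do.call(rbind, ml_rows)
    estimates <- rbind(estimates, ml_est)
    log <- c(log, sprintf("estimate (ml): %d curves, %d refusal(s)",
                          nrow(ml_est), sum(ml_est$status != "ok")))
  }

  na_contrast <- function(vision) data.frame(
    vision = vision, n_pairs = 0L, n_excluded = NA_integer_,
    median_diff = NA_real_, mean_diff = NA_real_,
    p_median = NA_real_, p_median_bonferroni = NA_real_,
    p_mean = NA_real_, p_mean_bonferroni = NA_real_,
    ci_median_lower = NA_real_, ci_median_upper = NA_real_,
    ci_mean_lower = NA_real_, ci_mean_upper = NA_real_)
  run_contrast <- function(method, vision, seed) {
    out <- tryCatch(
      compare_occlusion(estimates[estimates$method == method, ],
                        vision, config, seed = seed),
      error = function(e) {
        log <<- c(log, sprintf("compare (%s, %s): skipped — %s",
                               method, vision, conditionMessage(e)))
        na_contrast(vision)
      })
    cbind(method = method, out)
  }
  comps <- list(run_contrast("heuristic", "normal", seeds[4]),
                run_contrast("heuristic", "degraded", seeds[4]))
  if (isTRUE(config$ml))
    comps[[length(comps) + 1]] <- run_contrast("ml", "normal", seeds[5])
  comparisons <- do.call(rbind, comps)
  log <- c(log, sprintf("compare: %d contrast(s)", nrow(comparisons)))

  res <- structure(list(
    config = config,
    ground_truth = cohort$ground_truth,
    responses = ana$responses,
    estimates = estimates,
    comparisons = comparisons,
    ml_model = ml_model,
    log = log
  ), class = "study_results")
  if (!is.null(output_dir)) write_study_results(res, output_dir)
  res
}

#' @export
print.study_results <- function(x, ...) {
  cat("Synthetic VEP acuity study\n")
  for (l in x$log) cat(" ", l, "\n")
  cat("\nOcclusion contrasts (translucent - opaque, logMAR):\n")
  print(x$comparisons[, c("method", "vision", "n_pairs", "median_diff",
                          "mean_diff", "p_median", "p_mean")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
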