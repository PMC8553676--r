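# the four experimental conditions, and the balanced 4x4 Latin square used
# to counterbalance their order across participants
study_conditions <- function() {
  data.frame(vision = rep(c("normal", "degraded"), each = 2),
             occlusion = rep(c("opaque", "translucent"), 2),
             condition = c("normal.opaque", "normal.translucent",
                           "degraded.opaque", "degraded.translucent"))
}

condition_orders <- function() {
  sq <- rbind(c(1, 2, 4, 3),
              c(2, 3, 1, 4),
              c(3, 4, 2, 1),
              c(4, 1, 3, 2))
  conds <- study_conditions()$condition
  lapply(seq_len(4), function(i) conds[sq[i, ]])
}

#' Generate a synthetic study cohort
#'
#' Simulates the full 2x2 within-participant design: every participant is
#' measured with normal and degraded vision, each under opaque and
#' translucent contralateral occlusion.  Translucent conditions carry a
#' ground-truth logMAR shift of `effect` (negative = better acuity with
#' translucent occlusion).  Condition order is counterbalanced across
#' participants with a balanced Latin square of the four conditions.
#'
#' Per participant, normal-vision logMAR is drawn from
#' `N(logmar_mean, logmar_sd)` and the degradation shift from
#' `N(degradation_mean, degradation_sd)`; the peak response amplitude
#' gets mild log-normal between-subject variation.
#'
#' @param n_participants number of participants, >= 2
#' @param effect translucent-occlusion logMAR shift (the planted effect)
#' @param stimulus a [stimulus_set()]
#' @param seed cohort RNG seed; the dataset is byte-identical on
#'   regeneration with the same arguments
#' @param logmar_mean,logmar_sd distribution of normal-vision logMAR
#' @param degradation_mean,degradation_sd distribution of the
#'   degraded-vision shift (default centred on 1.06, the acuity loss of a
#'   strong diffusing filter)
#' @param peak_amplitude median tuning-curve peak amplitude, uV
#' @param noise_sd EEG noise sd, uV
#' @param blink_rate blink artifacts per minute
#' @param conversion_factor decimal acuity per cpd used to plant limits
#' @param fidelity `"recording"` simulates raw time series
#'   ([simulate_recording()], 6 per condition); `"curve"` simulates at
#'   the spectral-bin level ([simulate_tuning_curve()]), far faster
#' @return an object of class `vep_cohort`: `participants` (each with
#'   `model`, `order`, `conditions` holding recordings or curves),
#'   `ground_truth` (data frame: participant, vision, occlusion,
#'   condition, order_position, true_logmar), plus the generating
#'   parameters
#' @export
generate_cohort <- function(n_participants = 16, effect = -0.06,
                            stimulus = stimulus_set(), seed = 1L,
                            logmar_mean = 0, logmar_sd = 0.08,
                            degradation_mean = 1.06, degradation_sd = 0.05,
                            peak_amplitude = 10, noise_sd = 5,
                            blink_rate = 2,
                            conversion_factor = default_conversion_factor(),
                            fidelity = c("recording", "curve")) {
  fidelity <- match.arg(fidelity)
  if (n_participants < 2) stop("need at least 2 participants")
  conds <- study_conditions()
  orders <- condition_orders()
  with_local_seed(seed, {
    participants <- vector("list", n_participants)
    gt <- list()
    for (i in seq_len(n_participants)) {
      model <- participant_model(
        true_logmar_normal = stats::rnorm(1, logmar_mean, logmar_sd),
        degradation_delta = stats::rnorm(1, degradation_mean, degradation_sd),
        occlusion_delta = effect,
        peak_amplitude = peak_amplitude * stats::rlnorm(1, 0, 0.15),
        noise_sd = noise_sd,
        blink_rate = blink_rate,
        seed = draw_seeds(1)
      )
      order <- orders[[(i - 1) %% 4 + 1]]
      cond_data <- list()
      for (j in seq_len(nrow(conds))) {
        cn <- conds$condition[j]
        lm <- condition_logmar(model, conds$vision[j], conds$occlusion[j])
        data <- if (fidelity == "recording") {
          seeds <- draw_seeds(length(stimulus$check_sizes))
          lapply(seq_along(stimulus$check_sizes), function(k) {
            simulate_recording(model, stimulus, stimulus$check_sizes[k],
                               condition_logmar = lm,
                               conversion_factor = conversion_factor,
                               seed = seeds[k])
          })
        } else {
          simulate_tuning_curve(model, stimulus, condition_logmar = lm,
                                conversion_factor = conversion_factor,
                                seed = draw_seeds(1))
        }
        cond_data[[cn]] <- list(vision = conds$vision[j],
                                occlusion = conds$occlusion[j],
                                true_logmar = lm,
                                data = data)
        gt[[length(gt) + 1]] <- data.frame(
          participant = i, vision = conds$vision[j],
          occlusion = conds$occlusion[j], condition = cn,
          order_position = match(cn, order), true_logmar = lm)
      }
      participants[[i]] <- list(model = model, order = order,
                                conditions = cond_data)
    }
    structure(list(
      participants = participants,
      ground_truth = do.call(rbind, gt),
      stimulus = stimulus,
      effect = effect,
      conversion_factor = conversion_factor,
      fidelity = fidelity,
      seed = as.integer(seed)
    ), class = "vep_cohort")
  })
}

#' @export
print.vep_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic VEP cohort: %d participants x 4 conditions (%s fidelity)\n",
    length(x$participants), x$fidelity))
  cat(sprintf("  planted translucent-occlusion effect %+0.3f logMAR, seed %d\n",
              x$effect, x$seed))
  invisible(x)
}
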