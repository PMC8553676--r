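#' Define a simulated participant
#'
#' Ground-truth model of one observer for the synthetic SSVEP generator.
#' Acuity in a given experimental condition is
#' `true_logmar_normal + degradation_delta` (degraded-vision conditions)
#' `+ occlusion_delta` (translucent-occlusion conditions).  The tuning
#' curve of the observer's steady-state response declines linearly in
#' log spatial frequency and reaches zero at the spatial-frequency limit
#' implied by the condition's logMAR (see [simulate_recording()]).
#'
#' @param true_logmar_normal logMAR acuity with normal vision
#' @param degradation_delta logMAR shift added in degraded-vision
#'   conditions; the default 1.06 emulates a diffusing filter that
#'   degrades acuity to about 0.09 decimal
#' @param occlusion_delta logMAR shift added in translucent-occlusion
#'   conditions (the simulated effect under test; negative = better
#'   acuity with translucent occlusion)
#' @param peak_amplitude response amplitude at the tuning-curve peak, uV
#' @param noise_sd standard deviation of the additive white EEG noise, uV
#' @param blink_rate blink artifacts per minute
#' @param seed integer seed making this participant's recordings
#'   reproducible
#' @return an object of class `vep_participant`
#' @export
participant_model <- function(true_logmar_normal = 0,
                              degradation_delta = 1.06,
                              occlusion_delta = 0,
                              peak_amplitude = 10,
                              noise_sd = 5,
                              blink_rate = 2,
                              seed = 1L) {
  stopifnot(is.finite(true_logmar_normal), is.finite(degradation_delta),
            is.finite(occlusion_delta))
  if (!is.numeric(peak_amplitude) || peak_amplitude <= 0)
    stop("`peak_amplitude` must be > 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0")
  if (!is.numeric(blink_rate) || blink_rate < 0)
    stop("`blink_rate` must be >= 0")
  structure(list(
    true_logmar_normal = true_logmar_normal,
    degradation_delta = degradation_delta,
    occlusion_delta = occlusion_delta,
    peak_amplitude = peak_amplitude,
    noise_sd = noise_sd,
    blink_rate = blink_rate,
    seed = as.integer(seed)
  ), class = "vep_participant")
}

#' Ground-truth logMAR of a participant in one condition
#'
#' @param participant a [participant_model()]
#' @param vision `"normal"` or `"degraded"`
#' @param occlusion `"opaque"` or `"translucent"` (contralateral eye)
#' @return the condition's true logMAR
#' @export
condition_logmar <- function(participant,
                             vision = c("normal", "degraded"),
                             occlusion = c("opaque", "translucent")) {
  stopifnot(inherits(participant, "vep_participant"))
  vision <- match.arg(vision)
  occlusion <- match.arg(occlusion)
  lm <- participant$true_logmar_normal
  if (vision == "degraded") lm <- lm + participant$degradation_delta
  if (occlusion == "translucent") lm <- lm + participant$occlusion_delta
  lm
}

#' @export
print.vep_participant <- function(x, ...) {
  cat("Simulated VEP participant\n")
  cat(sprintf("  logMAR normal %.3f, degradation +%.2f, occlusion shift %+.3f\n",
              x$true_logmar_normal, x$degradation_delta, x$occlusion_delta))
  cat(sprintf("  peak amplitude %.1f uV, noise sd %.1f uV, %.1f blinks/min, seed %d\n",
              x$peak_amplitude, x$noise_sd, x$blink_rate, x$seed))
  invisible(x)
}
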