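#' Scale-free feature vector of a tuning curve
#'
#' Encodes a tuning curve for the acuity regressor: the six corrected
#' amplitudes normalized by their maximum (so the vector is invariant to
#' any common amplitude rescaling), the six effective significance flags,
#' the six log10 spatial frequencies, and a final validity sentinel that
#' is 1 for a curve with a positive amplitude scale and 0 for an all-zero
#' curve.  The absolute amplitude scale (uV) is kept as the `"scale"`
#' attribute for inspection but is not part of the model input.
#'
#' @param curve a `tuning_curve` with 6 points
#' @return a named numeric vector of length 19 (class `curve_features`)
#'   with attribute `scale`
#' @export
featurize <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  pts <- curve$points
  if (nrow(pts) != 6)
    stop("the acuity regressor expects 6-point tuning curves, got ",
         nrow(pts))
  amps <- pts$amplitude_corrected
  scale <- max(amps)
  norm <- if (scale > 0) amps / scale else rep(0, length(amps))
  v <- c(norm,
         as.numeric(effective_significance(curve)),
         pts$log_sf,
         as.numeric(scale > 0))
  names(v) <- c(paste0("amp", 1:6), paste0("sig", 1:6),
                paste0("logsf", 1:6), "valid")
  attr(v, "scale") <- scale
  class(v) <- "curve_features"
  v
}

# highest effectively significant log_sf, the validity coordinate used by
# the range guard (-Inf when no point is significant)
top_significant_log_sf <- function(curve) {
  sig <- effective_significance(curve)
  if (!any(sig)) -Inf else max(curve$points$log_sf[sig])
}

#' Simulate a training corpus of tuning curves with known acuity
#'
#' Draws participants with ground-truth logMAR uniform over
#' `logmar_range` and simulates one tuning curve each via the fast
#' spectral-bin generator ([simulate_tuning_curve()]).  The regression
#' target is the curve's ground-truth logMAR, optionally jittered to
#' emulate behavioral measurement error.
#'
#' @param n number of curves
#' @param logmar_range range of ground-truth logMAR values
#' @param stimulus a [stimulus_set()]
#' @param noise_sd EEG noise sd, uV (0 = noise-free corpus)
#' @param peak_amplitude tuning-curve peak amplitude, uV
#' @param behavioral_sd sd of jitter added to the target logMAR
#' @param conversion_factor decimal acuity per cpd used to plant limits
#' @param seed RNG seed
#' @return a list with `curves` (list of `tuning_curve`), `logmar`
#'   (targets), `true_logmar` (unjittered ground truth)
#' @export
make_training_corpus <- function(n = 300,
                                 logmar_range = c(-0.2, 0.4),
                                 stimulus = stimulus_set(),
                                 noise_sd = 5,
                                 peak_amplitude = 10,
                                 behavioral_sd = 0,
                                 conversion_factor = default_conversion_factor(),
                                 seed = 1L) {
  stopifnot(n >= 1, length(logmar_range) == 2,
            logmar_range[1] < logmar_range[2])
  with_local_seed(seed, {
    true_lm <- stats::runif(n, logmar_range[1], logmar_range[2])
    curves <- lapply(seq_len(n), function(i) {
      p <- participant_model(true_logmar_normal = true_lm[i],
                             peak_amplitude = peak_amplitude,
                             noise_sd = noise_sd,
                             blink_rate = 0)
      simulate_tuning_curve(p, stimulus, condition_logmar = true_lm[i],
                            conversion_factor = conversion_factor,
                            seed = NULL)
    })
    target <- true_lm +
      if (behavioral_sd > 0) stats::rnorm(n, 0, behavioral_sd) else 0
    list(curves = curves, logmar = target, true_logmar = true_lm)
  })
}

#' Train the neural-network acuity regressor
#'
#' Fits a single-hidden-layer feed-forward network (via [nnet::nnet()])
#' mapping scale-free tuning-curve features to behavioral logMAR by
#' least squares.  The model records its range of validity: the span of
#' training logMAR values and of the highest-significant-point log
#' spatial frequency, both enforced at prediction time (see
#' [predict.vep_acuity_net()]).
#'
#' @param curves list of `tuning_curve` objects (>= 100)
#' @param logmar corresponding behavioral logMAR targets
#' @param size hidden units
#' @param decay weight decay
#' @param maxit training iterations
#' @param seed RNG seed for weight initialization (reproducible)
#' @return an object of class `vep_acuity_net`
#' @export
train_acuity_model <- function(curves, logmar, size = 8, decay = 1e-3,
                               maxit = 500, seed = 1L) {
  stopifnot(is.list(curves), length(curves) == length(logmar))
  if (length(curves) < 100)
    stop("need at least 100 training pairs, got ", length(curves))
  if (!all(is.finite(logmar))) stop("training targets must be finite")
  if (diff(range(logmar)) == 0)
    stop("degenerate corpus: all training targets identical")
  x <- t(vapply(curves, function(cv) as.numeric(featurize(cv)),
                numeric(19)))
  colnames(x) <- names(featurize(curves[[1]]))
  top_sf <- vapply(curves, top_significant_log_sf, numeric(1))
  fit <- with_local_seed(seed,
    nnet::nnet(x, logmar, size = size, decay = decay, maxit = maxit,
               linout = TRUE, trace = FALSE))
  structure(list(
    net = fit,
    training_range = range(logmar),
    validity_log_sf = range(top_sf[is.finite(top_sf)]),
    n_curves = length(curves),
    size = size, decay = decay, maxit = maxit, seed = as.integer(seed)
  ), class = "vep_acuity_net")
}

#' @export
print.vep_acuity_net <- function(x, ...) {
  cat(sprintf("VEP acuity regressor: %d hidden units, %d training curves\n",
              x$size, x$n_curves))
  cat(sprintf("  trained logMAR range [%.3f, %.3f], seed %d\n",
              x$training_range[1], x$training_range[2], x$seed))
  invisible(x)
}

#' Predict acuity from a tuning curve, with a range-of-validity guard
#'
#' Returns a logMAR prediction only when the curve lies inside the
#' model's range of validity; otherwise an explicit typed refusal (not
#' an error), because a network trained on one acuity range produces
#' meaningless extrapolations outside it.  Two guards apply: (input) the
#' curve's highest significant point must fall within the span seen in
#' training (within half a typical check-size grid step), and a curve
#' with no significant point is always refused; (output) the predicted
#' logMAR must fall within the training target range plus `margin`.
#'
#' @param object a trained `vep_acuity_net`
#' @param curve a `tuning_curve`
#' @param margin tolerated logMAR excursion beyond the training range
#' @param ... unused
#' @return a list with `status` (`"ok"` or `"refused"`), `logmar`
#'   (`NA` on refusal), `reason`, and the model's `training_range`
#' @export
predict.vep_acuity_net <- function(object, curve, margin = 0.1, ...) {
  stopifnot(inherits(curve, "tuning_curve"))
  refuse <- function(reason) list(status = "refused", logmar = NA_real_,
                                  reason = reason,
                                  training_range = object$training_range)
  top_sf <- top_significant_log_sf(curve)
  if (!is.finite(top_sf))
    return(refuse("no significant tuning-curve point; outside the model's range of validity"))
  sf_margin <- 0.16  # about half a factor-2 check-size step in log10 units
  if (top_sf < object$validity_log_sf[1] - sf_margin ||
      top_sf > object$validity_log_sf[2] + sf_margin)
    return(refuse(sprintf(
      "curve's highest significant point (log SF %.2f) outside the training support [%.2f, %.2f]",
      top_sf, object$validity_log_sf[1], object$validity_log_sf[2])))
  x <- matrix(as.numeric(featurize(curve)), nrow = 1)
  pred <- as.numeric(stats::predict(object$net, x))
  lo <- object$training_range[1] - margin
  hi <- object$training_range[2] + margin
  if (pred < lo || pred > hi)
    return(refuse(sprintf(
      "prediction %.3f logMAR outside the trained range [%.3f, %.3f] (margin %.2f)",
      pred, object$training_range[1], object$training_range[2], margin)))
  list(status = "ok", logmar = pred, reason = NA_character_,
       training_range = object$training_range)
}
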