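#' Build a spatial-frequency tuning curve
#'
#' Orders per-check-size spectral responses by increasing log spatial
#' frequency.  Responses with `status != "ok"` (no usable segments) are
#' dropped with a warning; at least two usable responses with distinct
#' spatial frequencies are required.
#'
#' @param responses a list of [spectral_response()] objects
#' @return an object of class `tuning_curve`: a list with `points` (a
#'   data frame, one row per check size, ascending `log_sf`) and
#'   `overrides` (indices forced non-significant, initially empty)
#' @export
build_curve <- function(responses) {
  if (inherits(responses, "spectral_response")) responses <- list(responses)
  stopifnot(length(responses) >= 1,
            all(vapply(responses, inherits, TRUE, "spectral_response")))
  ok <- vapply(responses, function(r) identical(r$status, "ok"), TRUE)
  if (any(!ok)) {
    warning(sum(!ok), " response(s) without usable data dropped from curve")
    responses <- responses[ok]
  }
  if (length(responses) < 2)
    stop("need at least 2 usable responses to build a tuning curve")
  pts <- do.call(rbind, lapply(responses, function(r) {
    data.frame(check_size = r$check_size,
               spatial_frequency = r$spatial_frequency,
               log_sf = r$log_sf,
               amplitude_raw = r$amplitude_raw,
               phase = r$phase,
               noise_amplitude = r$noise_amplitude,
               amplitude_corrected = r$amplitude_corrected,
               power_corrected = r$power_corrected,
               p_value = r$p_value,
               significant = r$significant,
               n_segments_kept = r$n_segments_kept,
               n_segments_rejected = r$n_segments_rejected)
  }))
  dup <- duplicated(pts$spatial_frequency)
  if (any(dup))
    stop("duplicate spatial frequency for check size(s) ",
         paste(pts$check_size[dup], collapse = ", "), " arcmin")
  pts <- pts[order(pts$log_sf), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, overrides = integer(0)),
            class = "tuning_curve")
}

#' Rebuild a tuning curve from its tabular form
#'
#' Inverse of `as.data.frame()` on a `tuning_curve`: accepts the
#' one-row-per-check-size table written by [write_responses()] and
#' restores the curve object, so any pipeline stage can be re-run from
#' persisted intermediates.
#'
#' @param points a data frame with at least `spatial_frequency`,
#'   `amplitude_corrected`, `significant` columns
#' @return a `tuning_curve`
#' @export
curve_from_table <- function(points) {
  stopifnot(is.data.frame(points), nrow(points) >= 2,
            all(c("spatial_frequency", "amplitude_corrected", "significant")
                %in% names(points)))
  if (anyDuplicated(points$spatial_frequency))
    stop("duplicate spatial frequencies in table")
  if (is.null(points$log_sf)) points$log_sf <- log10(points$spatial_frequency)
  pts <- points[order(points$log_sf), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, overrides = integer(0)),
            class = "tuning_curve")
}

#' @export
as.data.frame.tuning_curve <- function(x, ...) {
  pts <- x$points
  pts$overridden <- seq_len(nrow(pts)) %in% x$overrides
  pts
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat("VEP tuning curve (", nrow(x$points), " check sizes)\n", sep = "")
  eff <- effective_significance(x)
  flag <- ifelse(eff, "*", ifelse(x$points$significant, "(x)", " "))
  df <- data.frame(sf_cpd = signif(x$points$spatial_frequency, 4),
                   amp_corr_uV = signif(x$points$amplitude_corrected, 3),
                   p = signif(x$points$p_value, 3),
                   sig = flag)
  print(df, row.names = FALSE)
  if (length(x$overrides))
    cat("  overridden (forced non-significant):",
        paste(x$overrides, collapse = ", "), "\n")
  invisible(x)
}

#' Effective significance of tuning-curve points
#'
#' A point is effectively significant iff its single-test p-value is
#' below alpha and it has not been overridden via [flag_spurious()].
#'
#' @param curve a `tuning_curve`
#' @return logical vector, one entry per point
#' @export
effective_significance <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  sig <- curve$points$significant
  sig[curve$overrides] <- FALSE
  sig
}

#' Override spurious significances on a tuning curve
#'
#' With many unresolvable check sizes (degraded vision), isolated
#' high-spatial-frequency points reach significance by chance (multiple
#' testing).  `manual` mode forces exactly the given point indices
#' non-significant, mirroring manual correction of obvious cases.
#' `auto` mode applies a convenience rule: a significant point is
#' overridden iff it is separated from the contiguous low-spatial-
#' frequency block of retained significant points by at least two
#' consecutive non-significant points.
#'
#' @param curve a `tuning_curve`
#' @param mode `"manual"` or `"auto"`
#' @param indices for manual mode, point indices (ascending-`log_sf`
#'   order) to force non-significant
#' @return the curve with its `overrides` updated
#' @export
flag_spurious <- function(curve, mode = c("auto", "manual"),
                          indices = integer(0)) {
  stopifnot(inherits(curve, "tuning_curve"))
  mode <- match.arg(mode)
  n <- nrow(curve$points)
  if (mode == "manual") {
    indices <- as.integer(indices)
    if (length(indices) && (min(indices) < 1 || max(indices) > n))
      stop("override index out of range 1..", n)
    curve$overrides <- sort(unique(c(curve$overrides, indices)))
    return(curve)
  }
  sig <- effective_significance(curve)
  first <- which(sig)[1]
  if (is.na(first)) return(curve)
  last_kept <- first
  over <- integer(0)
  for (i in seq(first + 1, length.out = max(0, n - first))) {
    if (!sig[i]) next
    if (i - last_kept - 1 >= 2) over <- c(over, i) else last_kept <- i
  }
  curve$overrides <- sort(unique(c(curve$overrides, over)))
  curve
}

#' Extrapolate the tuning curve to its spatial-frequency limit
#'
#' Stepwise heuristic: (1) the peak is the effectively significant point
#' with the largest noise-corrected amplitude (ties broken toward lower
#' spatial frequency); (2) the fit set runs from the peak through the
#' highest-spatial-frequency significant point, plus the first
#' non-significant point beyond it if it exists and carries a positive
#' corrected amplitude (a floored-to-zero point adds no response
#' information); (3) a least-squares line of corrected amplitude versus
#' log10 spatial frequency is fitted over the set; (4) the limit is
#' `10^x0` where `x0` is the line's abscissa intercept.
#'
#' The outcome is `no_estimate` when no point is effectively
#' significant, when fewer than two fit points remain, or when the
#' fitted slope is not negative.
#'
#' The fit is computed in closed form as
#' `x0 = mean(x) - mean(y) * Sxx / Sxy`, which is algebraically
#' independent of the amplitude scale: rescaling every amplitude by a
#' common factor cancels exactly.
#'
#' @param curve a `tuning_curve` (overrides already applied)
#' @return a list with `status` (`"ok"`/`"no_estimate"`), `sf_limit`
#'   (cpd), `slope` (uV per log10 cpd), `intercept_log_sf`, `fit_points`
#'   (indices used), `reason` (for `no_estimate`)
#' @export
fit_sf_limit <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  pts <- curve$points
  sig <- effective_significance(curve)
  no_est <- function(reason) list(status = "no_estimate", reason = reason,
                                  sf_limit = NA_real_, slope = NA_real_,
                                  intercept_log_sf = NA_real_,
                                  fit_points = integer(0))
  if (!any(sig)) return(no_est("no significant response at any check size"))
  sig_idx <- which(sig)
  amps <- pts$amplitude_corrected
  peak <- sig_idx[which.max(amps[sig_idx])]   # which.max -> lowest-SF tie
  last_sig <- max(sig_idx)
  fit_idx <- seq(peak, last_sig)
  if (last_sig < nrow(pts) && amps[last_sig + 1] > 0)
    fit_idx <- c(fit_idx, last_sig + 1L)
  if (length(fit_idx) < 2)
    return(no_est("fewer than 2 points available for the line fit"))
  x <- pts$log_sf[fit_idx]
  y <- amps[fit_idx]
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  sxy <- sum((x - xm) * (y - ym))
  slope <- sxy / sxx
  if (!is.finite(slope) || slope >= 0)
    return(no_est("fitted slope is not negative"))
  x0 <- xm - ym * sxx / sxy
  list(status = "ok", reason = NA_character_,
       sf_limit = 10^x0, slope = slope, intercept_log_sf = x0,
       fit_points = fit_idx)
}

#' Convert a spatial-frequency limit to decimal and logMAR acuity
#'
#' `decimal = conversion_factor * sf_limit`, clipped to at most
#' `clip_ceiling` (estimates far beyond the stimulus range are
#' imprecise and clinically indistinct), then `logmar = -log10(decimal)`.
#' The conversion factor has no default here: it is a calibration
#' constant that must be chosen explicitly (see
#' [default_conversion_factor()]).
#'
#' @param sf_limit spatial-frequency limit, cpd, > 0
#' @param conversion_factor decimal acuity per cpd, > 0
#' @param clip_ceiling maximum reportable decimal acuity (default 1.6,
#'   i.e. logMAR >= -0.2)
#' @return a list with `decimal_acuity`, `logmar`, `clipped`
#' @examples
#' to_acuity(17.6, 1 / 17.6)  # decimal 1.0, logMAR 0
#' @export
to_acuity <- function(sf_limit, conversion_factor, clip_ceiling = 1.6) {
  if (!is.numeric(sf_limit) || sf_limit <= 0)
    stop("`sf_limit` must be > 0")
  if (!is.numeric(conversion_factor) || conversion_factor <= 0)
    stop("`conversion_factor` must be > 0")
  decimal <- conversion_factor * sf_limit
  clipped <- decimal > clip_ceiling
  if (clipped) decimal <- clip_ceiling
  list(decimal_acuity = decimal, logmar = -log10(decimal), clipped = clipped)
}

#' Acuity estimate from a tuning curve (heuristic algorithm)
#'
#' Runs [fit_sf_limit()] and [to_acuity()] and assembles the complete
#' estimate record.
#'
#' @param curve a `tuning_curve`
#' @param conversion_factor decimal acuity per cpd (explicit; see
#'   [to_acuity()])
#' @param clip_ceiling maximum reportable decimal acuity
#' @return an object of class `acuity_estimate` with `status`
#'   (`"ok"`/`"no_estimate"`), `sf_limit`, `decimal_acuity`, `logmar`,
#'   `clipped`, `slope`, `fit_points`, `method = "heuristic"`
#' @export
estimate_acuity <- function(curve, conversion_factor, clip_ceiling = 1.6) {
  fit <- fit_sf_limit(curve)
  if (fit$status != "ok") {
    return(structure(list(
      status = "no_estimate", reason = fit$reason,
      sf_limit = NA_real_, decimal_acuity = NA_real_, logmar = NA_real_,
      clipped = NA, slope = NA_real_, fit_points = integer(0),
      method = "heuristic"
    ), class = "acuity_estimate"))
  }
  ac <- to_acuity(fit$sf_limit, conversion_factor, clip_ceiling)
  structure(list(
    status = "ok", reason = NA_character_,
    sf_limit = fit$sf_limit,
    decimal_acuity = ac$decimal_acuity,
    logmar = ac$logmar,
    clipped = ac$clipped,
    slope = fit$slope,
    fit_points = fit$fit_points,
    method = "heuristic"
  ), class = "acuity_estimate")
}

#' @export
print.acuity_estimate <- function(x, ...) {
  if (x$status != "ok") {
    cat("Acuity estimate (", x$method, "): no estimate — ", x$reason, "\n",
        sep = "")
    return(invisible(x))
  }
  cat(sprintf("Acuity estimate (%s): logMAR %.3f (decimal %.3f%s)",
              x$method, x$logmar, x$decimal_acuity,
              if (isTRUE(x$clipped)) ", clipped" else ""))
  if (!is.na(x$sf_limit))
    cat(sprintf(", SF limit %.2f cpd", x$sf_limit))
  cat("\n")
  invisible(x)
}
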