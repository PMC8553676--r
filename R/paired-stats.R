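#' Paired within-participant differences
#'
#' Holds per-participant logMAR differences between two conditions
#' (A minus B).  Participants with a missing estimate (`NA`) in either
#' condition are excluded pairwise before any testing; the mask records
#' who was excluded.
#'
#' @param a,b per-participant values for the two conditions (`NA` for
#'   `no_estimate` outcomes)
#' @param id optional participant identifiers
#' @return an object of class `paired_differences` with `diffs` (the
#'   complete pairs), `id`, `n`, `n_missing`, `missing_id`
#' @export
paired_differences <- function(a, b, id = seq_along(a)) {
  stopifnot(length(a) == length(b), length(id) == length(a))
  miss <- is.na(a) | is.na(b)
  structure(list(
    diffs = (a - b)[!miss],
    id = id[!miss],
    n = sum(!miss),
    n_missing = sum(miss),
    missing_id = id[miss]
  ), class = "paired_differences")
}

#' @export
print.paired_differences <- function(x, ...) {
  cat(sprintf("Paired differences: n = %d complete pairs (%d excluded)\n",
              x$n, x$n_missing))
  cat(sprintf("  median %+.4f, mean %+.4f\n",
              stats::median(x$diffs), mean(x$diffs)))
  invisible(x)
}

as_paired <- function(diffs) {
  if (inherits(diffs, "paired_differences")) return(diffs)
  stopifnot(is.numeric(diffs))
  paired_differences(diffs, rep(0, length(diffs)))
}

# statistic over every sign pattern in a block of pattern indices
perm_stats <- function(signs, d, statistic) {
  if (statistic == "mean") as.numeric(signs %*% d) / length(d)
  else apply(sweep(signs, 2, d, `*`), 1, stats::median)
}

#' Paired permutation test by sign flipping
#'
#' Repeated-measures test of the null hypothesis that the paired
#' differences are symmetric about zero: each participant's difference
#' is multiplied by +-1 and the test statistic (median or mean)
#' recomputed.  All 2^n sign patterns are enumerated when n is at most
#' `exhaustive_max`; otherwise `n_permutations` Monte-Carlo patterns are
#' drawn (seeded), with the identity pattern always counted.  The
#' two-sided p-value is the proportion of patterns whose |statistic|
#' reaches the observed |statistic|.
#'
#' @param diffs a [paired_differences()] or numeric vector of differences
#' @param statistic `"median"` or `"mean"`
#' @param n_permutations Monte-Carlo draws when enumeration is infeasible
#' @param seed RNG seed for the Monte-Carlo branch
#' @param exhaustive_max largest n for exhaustive 2^n enumeration
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#' @return a list (class `vep_permutation_test`) with `p_value`,
#'   `observed`, `statistic`, `n`, `method` (`"exhaustive"` or
#'   `"monte_carlo"`), `n_patterns`
#' @export
permutation_test <- function(diffs, statistic = c("median", "mean"),
                             n_permutations = 1e5, seed = NULL,
                             exhaustive_max = 20,
                             alternative = c("two.sided", "less", "greater")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  pd <- as_paired(diffs)
  d <- pd$diffs
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  stat_fun <- if (statistic == "mean") mean else stats::median
  obs <- stat_fun(d)
  tail_count <- function(s) switch(alternative,
    two.sided = sum(abs(s) >= abs(obs)),
    less      = sum(s <= obs),
    greater   = sum(s >= obs))
  if (n <= exhaustive_max) {
    total <- 2^n
    block_bits <- min(n, 14L)
    block <- 2^block_bits
    base_signs <- 1 - 2 * ((outer(0:(block - 1), 0:(block_bits - 1),
                                  function(i, j) i %/% 2^j)) %% 2)
    count <- 0
    for (start in seq(0, total - 1, by = block)) {
      hi_bits <- if (n > block_bits) {
        hi <- start %/% block
        1 - 2 * (((hi %/% 2^(0:(n - block_bits - 1))) %% 2))
      } else NULL
      signs <- if (is.null(hi_bits)) base_signs
               else cbind(base_signs,
                          matrix(hi_bits, block, n - block_bits, byrow = TRUE))
      count <- count + tail_count(perm_stats(signs, d, statistic))
    }
    p <- count / total
    method <- "exhaustive"; n_patterns <- total
  } else {
    p <- with_local_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                      n_permutations, n)
      (1 + tail_count(perm_stats(signs, d, statistic))) / (n_permutations + 1)
    })
    method <- "monte_carlo"; n_patterns <- n_permutations
  }
  structure(list(p_value = p, observed = obs, statistic = statistic,
                 n = n, method = method, n_patterns = n_patterns,
                 alternative = alternative),
            class = "vep_permutation_test")
}

#' @export
print.vep_permutation_test <- function(x, ...) {
  cat(sprintf(
    "Paired sign-flip permutation test (%s, %s): %s = %+.4f, n = %d, p = %.4g\n",
    x$method, x$alternative, x$statistic, x$observed, x$n, x$p_value))
  invisible(x)
}

#' Bootstrap confidence interval for a paired statistic
#'
#' Percentile bootstrap over participants: complete pairs are resampled
#' with replacement, the statistic recomputed, and the interval taken
#' from the empirical quantiles.  A bias-corrected accelerated (BCa)
#' variant is available behind `type`.
#'
#' @param diffs a [paired_differences()] or numeric vector
#' @param statistic `"median"` or `"mean"`
#' @param level confidence level
#' @param n_boot bootstrap replicates
#' @param seed RNG seed
#' @param type `"percentile"` (default) or `"bca"`
#' @return a list (class `vep_bootstrap_ci`) with `lower`, `upper`
#'   (always ordered lower <= upper), `observed`, `level`
#' @export
bootstrap_ci <- function(diffs, statistic = c("median", "mean"),
                         level = 0.95, n_boot = 1999, seed = NULL,
                         type = c("percentile", "bca")) {
  statistic <- match.arg(statistic)
  type <- match.arg(type)
  pd <- as_paired(diffs)
  d <- pd$diffs
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  stat_fun <- if (statistic == "mean") mean else stats::median
  obs <- stat_fun(d)
  with_local_seed(seed, {
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
    boots <- if (statistic == "mean") rowMeans(matrix(d[idx], n_boot, n))
             else apply(matrix(d[idx], n_boot, n), 1, stats::median)
    a <- (1 - level) / 2
    probs <- if (type == "percentile") c(a, 1 - a) else {
      z0 <- stats::qnorm(pmin(pmax(mean(boots < obs), 1 / n_boot),
                              1 - 1 / n_boot))
      jack <- vapply(seq_len(n), function(i) stat_fun(d[-i]), numeric(1))
      jm <- mean(jack)
      denom <- 6 * sum((jm - jack)^2)^1.5
      acc <- if (denom == 0) 0 else sum((jm - jack)^3) / denom
      zq <- stats::qnorm(c(a, 1 - a))
      stats::pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
    }
    ci <- unname(stats::quantile(boots, probs, type = 7))
    structure(list(lower = min(ci), upper = max(ci), observed = obs,
                   level = level, statistic = statistic, n = n,
                   n_boot = n_boot, type = type),
              class = "vep_bootstrap_ci")
  })
}

#' @export
print.vep_bootstrap_ci <- function(x, ...) {
  cat(sprintf("%d%% %s bootstrap CI for the %s: [%.4f, %.4f] (observed %+.4f, n = %d)\n",
              round(100 * x$level), x$type, x$statistic,
              x$lower, x$upper, x$observed, x$n))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `min(1, factor * p)`.  The study design compares the occlusion
#' contrast at two vision levels, hence the default factor 2.
#'
#' @param p p-value(s) in [0, 1]
#' @param factor number of tests in the family
#' @return adjusted p-value(s), capped at 1
#' @examples
#' bonferroni(0.030)  # 0.060
#' @export
bonferroni <- function(p, factor = 2) {
  stopifnot(all(p >= 0 & p <= 1), factor >= 1)
  pmin(1, factor * p)
}

#' Index of the most outlying paired difference
#'
#' The participant whose difference deviates most (in absolute value)
#' from the median difference.
#'
#' @param diffs a [paired_differences()] or numeric vector
#' @return index into the complete pairs
#' @export
most_outlying <- function(diffs) {
  d <- as_paired(diffs)$diffs
  which.max(abs(d - stats::median(d)))
}

#' Exclude one participant's difference
#'
#' Pairwise removal of a single data point (e.g. the most outlying one)
#' so downstream tests can be re-run on the reduced set.
#'
#' @param diffs a [paired_differences()] or numeric vector
#' @param index index into the complete pairs (defaults to
#'   [most_outlying()])
#' @return a `paired_differences` with n reduced by one
#' @export
exclude_outlier <- function(diffs, index = most_outlying(diffs)) {
  pd <- as_paired(diffs)
  if (length(index) != 1 || index < 1 || index > pd$n)
    stop("`index` must be a single index in 1..", pd$n)
  pd$diffs <- pd$diffs[-index]
  pd$id <- pd$id[-index]
  pd$n <- pd$n - 1L
  pd
}
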