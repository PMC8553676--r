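# vepacuity

Objective visual acuity estimation from steady-state visual evoked
potentials (VEPs), for visual electrophysiologists and vision scientists
who need an acuity estimate when psychophysical testing is unreliable —
and for anyone studying the estimation pipeline itself.

## The method

Checkerboards of six check sizes are presented in pattern-reversal mode
while the EEG is recorded in 1-s segments. Per check size, the pipeline:

1. rejects segments exceeding the 120-µV blink criterion;
2. averages the remaining segments coherently and reads the DFT bin at
   the first harmonic of the reversal rate, giving the response
   amplitude *A* (µV);
3. estimates the noise floor *N* from the mean power of the 2 nearest
   bins on each side of the harmonic, and corrects the response in the
   power domain, `A_c = sqrt(max(A² − N², 0))`;
4. tests significance with an F-ratio: under a Gaussian null,
   `A²/mean(neighbour power) ~ F(2, 2m)` for *m* neighbour bins
   (single-test α = 0.05).

Corrected amplitude against log₁₀ spatial frequency (one cycle = two
checks: `f [cpd] = 60 / (2 · check size [arcmin])`) is the **tuning
curve**. A stepwise heuristic selects the descending run of significant
points (from the peak through the highest significant spatial frequency,
plus the first non-significant point beyond it when informative), fits a
straight line, and extrapolates to the abscissa intercept `x₀` — the
**VEP spatial-frequency limit** `f_lim = 10^x₀`. Acuity follows as

```
decimal = k · f_lim          (k: calibration constant, decimal acuity per cpd)
decimal ← min(decimal, 1.6)  (clip; logMAR ≥ −0.2)
logMAR  = −log10(decimal)
```

If no point is significant, fewer than two fit points remain, or the
slope is not negative, the result is an explicit `no_estimate` outcome.
A one-hidden-layer neural-network regressor on scale-free curve features
provides a second estimate, refusing (rather than extrapolating) curves
outside its trained acuity range. Paired condition comparisons use
sign-flipping permutation tests (median/mean, exhaustive to 2^n for
n ≤ 20), percentile bootstrap intervals, and a factor-2 Bonferroni
adjustment.

Because clinical VEP data are not redistributable, the package includes a
synthetic SSVEP generator (`simulate_recording()`, `generate_cohort()`)
whose tuning function declines linearly in log spatial frequency to zero
at a planted, ground-truth SF limit — making recovery of the limit an
exact oracle for the whole pipeline.

## Worked example

One simulated participant (true logMAR 0.10), six recordings, tuning
curve and estimate:

```r
library(vepacuity)
stim <- stimulus_set()
p <- participant_model(true_logmar_normal = 0.10, noise_sd = 5,
                       blink_rate = 2, seed = 42)
recs <- lapply(stim$check_sizes, function(cs)
  simulate_recording(p, stim, cs, condition_logmar = 0.10))
curve <- build_curve(lapply(recs, analyze_recording))
print(curve)
#> VEP tuning curve (6 check sizes)
#>  sf_cpd amp_corr_uV        p sig
#>    0.75       6.380 3.70e-15   *
#>    1.50       4.880 3.18e-14   *
#>    3.00       3.370 6.07e-13   *
#>    6.00       1.870 6.82e-11   *
#>   12.00       0.359 2.56e-05   *
#>   24.00       0.000 6.91e-01
estimate_acuity(curve, conversion_factor = default_conversion_factor())
#> Acuity estimate (heuristic): logMAR 0.094 (decimal 0.805), SF limit 14.16 cpd
```

The amplitudes fall linearly in log spatial frequency; the extrapolated
limit (14.2 cpd) converts to logMAR 0.094, recovering the planted 0.10 to
within the noise of a single 8-minute session.

A full synthetic study — 16 participants, 2×2 design (normal/degraded
vision × translucent/opaque contralateral occlusion), with a planted
−0.06 logMAR translucent-occlusion effect:

```r
res <- run_study(study_config(seed = 5))
print(res)
#> Occlusion contrasts (translucent - opaque, logMAR):
#>     method   vision n_pairs median_diff mean_diff p_median   p_mean
#>  heuristic   normal      16     -0.0612   -0.0464  0.00391 1.16e-03
#>  heuristic degraded      11     -0.0544    0.0131  0.28906 8.86e-01
#>         ml   normal      16     -0.0630   -0.0635  0.00391 3.05e-05
```

The planted effect is recovered at normal vision by both estimators; at
degraded vision five participants yield no estimate in at least one
condition (n drops to 11) and no reliable effect is detected — the
hard-to-measure regime behaves as expected. `run_study(..., output_dir =)`
persists every intermediate table (responses, estimates, comparisons) as
CSV. A thin command-line wrapper lives in `inst/cli/vep-acuity.R`.

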