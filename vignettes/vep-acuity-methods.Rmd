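---
title: "Estimating visual acuity from steady-state VEP tuning curves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating visual acuity from steady-state VEP tuning curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When psychophysical acuity testing is unreliable — malingering, preverbal
children, suspected non-organic visual loss — visual acuity can be estimated
objectively from the EEG. Checkerboard stimuli of six decreasing check sizes
are presented in pattern-reversal mode while a steady-state visual evoked
potential (VEP) is recorded. If the pattern is resolved, the cortex responds
at the reversal rate; if it is too fine to resolve, no pattern-specific
response is evoked. Plotting first-harmonic response amplitude against log
spatial frequency yields a *tuning curve* whose descending limb can be
extrapolated to the spatial frequency at which the response vanishes — the
VEP spatial-frequency (SF) limit — and that limit converts to a decimal or
logMAR acuity estimate.

`vepacuity` implements this pipeline end to end, together with a synthetic
SSVEP generator with known ground truth, so that every stage — and the
pipeline as a whole — is testable without access to clinical recordings.

# The measurement model

## Segmentation and artifact rejection

A recording for one check size is divided into contiguous 1-s segments.
A segment is rejected iff its maximum absolute amplitude exceeds 120 µV
(`segment_and_reject()`), the standard blink criterion. "Maximum absolute
deviation from baseline" is our operationalization; a peak-to-peak variant
is available via `criterion = "peak_to_peak"`. If every segment is
rejected the recording yields an explicit *no usable data* outcome that
propagates as a missing tuning-curve point rather than an error.

## First-harmonic extraction

Accepted segments are averaged coherently in the time domain and the DFT
of the average is read out at the stimulation's first harmonic
(`first_harmonic()`). Because the stimulus constructor enforces a whole
number of response cycles per segment, the harmonic falls exactly on a DFT
bin; off-bin requests are rejected with a message naming that requirement.
Amplitudes are single-sided sinusoid amplitudes in µV (`2|X_k|/N`), so a
noise-free sinusoid of amplitude *A* is reported as exactly *A*. An
incoherent alternative (averaging per-segment amplitude spectra,
`averaging = "spectral"`) is provided for comparison; it does not cancel
noise and is not the default.

## Noise correction and significance

The background-EEG contribution at the harmonic is estimated from the
`k = 2` nearest bins on each side of the harmonic (4 bins total):
`noise_amplitude = sqrt(mean power of the neighbour bins)`. The reported
response is then corrected by power-domain subtraction floored at zero,

```
amplitude_corrected = sqrt(max(amplitude_raw^2 - noise_amplitude^2, 0))
```

Subtracting powers rather than voltages removes, in expectation, the
upward Rayleigh bias that additive noise imparts to a measured amplitude.
The *signed* power difference `power_corrected` is also reported; its mean
over noise-only recordings is zero, which is the unbiasedness property the
test suite checks. The floored amplitude itself is necessarily biased
upward under pure noise (the positive part of a zero-mean variable has
positive mean, about 41% of the noise power at k = 2); this is inherent to
any non-negative amplitude estimate and is why significance, not corrected
amplitude, decides which points count as responses.

Significance is tested with an F-ratio: under a circularly symmetric
Gaussian null, harmonic power over mean neighbour power is F(2, 2m)
distributed for m neighbour bins. With the default m = 4 the single-test
p-value is the upper tail of F(2, 8); the test is exact for white noise,
and the suite verifies a 5% false-positive rate empirically at α = 0.05.
Degenerate inputs follow two conventions: zero neighbour power with zero
signal gives p = 1, with positive signal p = 0. Both k and the test
statistic are configuration points; the published descriptions of this
analysis cite the neighbour-bin noise correction and significance
estimation without reprinting formulas, so the voltage-vs-power domain and
the exact neighbour count are reconstruction choices documented here.

## The heuristic extrapolation algorithm

`fit_sf_limit()` reconstructs the stepwise heuristic:

1. The *peak* is the effectively significant point with the largest
   corrected amplitude; ties go to the lower spatial frequency, which
   keeps more descending points in the fit.
2. The fit set runs from the peak through the highest-SF significant
   point, plus the first non-significant point beyond it, *if* that point
   carries a positive corrected amplitude. A point floored to exactly
   zero is excluded: it carries no response information, and including a
   hard zero would systematically drag the intercept upward (by
   0.05–0.07 log units on noise-free synthetic curves, where the planted
   limit is otherwise recovered exactly).
3. A least-squares line of corrected amplitude versus log10 spatial
   frequency is fitted over the set.
4. The SF limit is `10^x0` at the line's abscissa intercept.

The outcome is `no_estimate` — a typed status, not an error — when no
point is effectively significant, fewer than two fit points remain, or the
fitted slope is not negative.

The fit uses the closed form `x0 = mean(x) − mean(y)·Sxx/Sxy`, in which a
common rescaling of all amplitudes cancels algebraically. Rescaling by a
power of two is exact in floating point, and the limit is then reproduced
bit for bit; for arbitrary factors the inputs themselves are rounded, and
agreement is to rounding error (≲1e−12 relative). This is the strongest
form of the well-known property that a uniform percentage change of VEP
amplitude across all check sizes cannot move the acuity estimate.

## Spurious-significance overrides

Under degraded vision most check sizes are unresolvable, so chance
significances among many null tests become likely, and an isolated
high-SF "significant" point can wreck the extrapolation. Clinical practice
handles obvious cases by manually marking such points non-significant
before the algorithm runs; `flag_spurious(curve, "manual", indices)`
reproduces exactly that. The `"auto"` mode encodes the obvious cases as a
rule: a significant point is overridden iff it is separated from the
contiguous low-SF block of retained significant points by at least two
consecutive non-significant points. The full-study driver applies the auto
rule by default.

One subtlety found while validating: forcing the highest-SF significant
point non-significant *almost* never increases the fitted limit, but the
guarantee is not exact — when the override changes which point is the
appended non-significant one, removing a below-the-line point can raise
the intercept slightly (≤0.02 log units in our property tests, about 2% of
noisy curves). The tests assert exact non-increase only in the noise-free
case and bounded change with noise.

## Acuity conversion and clipping

`decimal = conversion_factor × sf_limit`, clipped to ≤1.6 (logMAR ≥ −0.2)
because values far beyond the stimulus range are imprecise and clinically
indistinct; then `logmar = −log10(decimal)`. Clipping happens after the
conversion and before the logMAR transform. The conversion factor is a
calibration constant: `to_acuity()` deliberately has no default, and
`default_conversion_factor()` (1/17.6 decimal acuity per cpd, i.e. decimal
1.0 at 17.6 cpd) is a documented placeholder that any clinical deployment
must replace with a locally calibrated value. The spatial-frequency
convention (one cycle = two checks along the edge; `×√2` diagonal variant
available) is absorbed by this same factor.

# The neural-network estimator

As a second route, `train_acuity_model()` fits a one-hidden-layer
feed-forward network (via `nnet`, 8 hidden units, weight decay 1e−3) that
maps tuning-curve features to behavioral logMAR. Features are scale-free
by construction: the six corrected amplitudes normalized by their maximum,
the six effective significance flags, the six log SFs, and a 0/1 validity
sentinel for the degenerate all-zero curve; the absolute µV scale is kept
only as an attribute. The architecture is a configuration point — the
contract is behavioral (prediction accuracy and the range guard), not
fidelity to any particular network.

A regression model trained on one acuity range produces meaningless
extrapolations outside it, so `predict()` refuses rather than
extrapolates: (input guard) the curve's highest significant point must lie
within the span seen in training, within half a check-size grid step
(0.16 log10 units), and a curve with no significant point is always
refused; (output guard) the predicted logMAR must fall within the training
range plus a 0.1 logMAR margin. A refusal is a typed outcome naming the
trained range. The input guard matters in practice: with realistic noise,
an isolated chance significance at high SF can make a far-out-of-range
curve look superficially plausible; after the standard spurious-override
step the refusal rate on out-of-range corpora is total in our tests.

# Paired statistics

The study design this pipeline serves is within-participant: each
participant contributes estimates under 2×2 conditions (normal/degraded
vision × translucent/opaque occlusion of the contralateral eye), and
inference concerns the per-participant logMAR difference between occlusion
conditions at each vision level. Participants with a `no_estimate` in
either member of a pair are excluded pairwise.

* `permutation_test()` — sign-flipping test of symmetry about zero, the
  exchangeability scheme appropriate for paired differences. All 2^n sign
  patterns are enumerated for n ≤ 20 (chunked, so memory stays bounded);
  larger n uses seeded Monte-Carlo with the identity pattern counted,
  p = (1 + #{|stat*| ≥ |stat|})/(B + 1). Two-sided by default; the
  statistic is the median or the mean. All-zero differences give p = 1
  under the inclusive counting convention. The median of an even count is
  the mean of the central pair (R's default).
* `bootstrap_ci()` — percentile bootstrap over participants, the default
  matching the classic resampling tradition; BCa behind a flag. Intervals
  are always reported `[lower, upper]` with lower ≤ upper. Percentile
  intervals undercover somewhat for very small n (a textbook property,
  visible in our calibration tests), which is worth remembering when n is
  a dozen participants.
* `bonferroni()` — `min(1, 2p)` for the two-vision-level family.
* `exclude_outlier()` — pairwise removal of the most outlying difference
  (largest absolute deviation from the median), for sensitivity analyses.

# The synthetic generator

`simulate_recording()` embeds a sinusoid at the first harmonic of the
reversal rate whose amplitude follows a tuning function that declines
linearly in log10 spatial frequency, reaching exactly zero at the SF limit
implied by the condition's ground-truth logMAR (via the inverse of the
acuity conversion), flat at `peak_amplitude` below the decline. The
decline spans 2 log10 units by default, which places the whole default
stimulus range on the descending limb for realistic acuities — so the
heuristic's straight-line extrapolation is exact by construction and
recovery of the planted limit is a clean oracle. Additive noise is white
Gaussian (an optional 1/f admixture is off by default, because white noise
is the model under which the significance test's calibration is exactly
checkable); blinks are 200-ms raised-cosine transients of 150–300 µV,
deliberately above the 120-µV criterion, at most one per segment, with a
Poisson count at `blink_rate`/min.

Defaults, chosen once as a realistic operating point and used by every
test: six check sizes 40…1.25 arcmin (geometric, factor 2 — 1.5 log10
units of spatial frequency, in the spirit of the extended-protocol
recommendation of about six sizes), 8 reversals/s, 1000 Hz sampling, 80
one-second segments per recording (8 min of EEG per condition), peak
amplitude 10 µV, noise 5 µV, 2 blinks/min. A reversal rate of 7.5/s is
common in practice; it requires 2-s segments for whole-cycle segments and
is accepted with them. Cohorts (`generate_cohort()`) draw normal-vision
logMAR from N(0, 0.08), the degradation shift from N(1.06, 0.05) —
emulating a strong diffusing filter that leaves roughly 0.09 decimal
acuity — apply the planted occlusion effect (default −0.06 logMAR) in
translucent conditions, add mild log-normal between-subject amplitude
variation, and counterbalance condition order with a balanced 4×4 Latin
square.

`simulate_tuning_curve()` is a fast path that samples harmonic and
neighbour bins directly from their exact sampling distribution under the
same model (signal phasor plus circular complex Gaussian noise with
per-quadrature sd `noise_sd·sqrt(2/(N·M))`), skipping the time domain; it
is statistically identical to the full pipeline for white noise without
blinks and is used for large corpora and calibration sweeps.

What the generator does *not* emulate — and what passing tests therefore
do not establish about clinical data: realistic VEP waveshape beyond the
first harmonic, alpha rhythms and non-stationary or correlated EEG noise,
electrode and montage effects, drifts of attention or fixation, and any
nonlinearity of the true amplitude-vs-SF relation. Recovery results on
synthetic curves are oracle checks of the algorithm, not accuracy claims
for patients.

# Problem sizes and numerical choices

The validation suite runs at desk scale, chosen to give each check solid
statistical resolution: 10⁴ pure-noise recordings for the type-I
calibration of the spectral test (99% binomial interval around α = 0.05);
100 planted limits for noise-free recovery (tolerance 0.02 log10 units)
and 100 default-SNR participants for the ≤0.2 logMAR mean-absolute-error
check; exhaustive-vs-Monte-Carlo permutation agreement at 10⁵ draws for
every n from 5 to 10 (tolerance 0.01); bootstrap coverage over 1000
datasets of 30 Gaussian differences (band 0.92–0.97); 10⁴ symmetric-null
datasets for the permutation test's own type-I rate. The full default
study (16 participants × 4 conditions × 6 check sizes, ML included) runs
in well under a minute of simulation plus a few seconds of statistics on
one core.

Other numerical conventions: segment rejection is strict (`> 120 µV`
rejects, 120.0 exactly is kept); the harmonic-bin whole-cycles check uses
a 1e−9 tolerance; sub-seeds for cohorts and stages are drawn from the
master seed's stream and kept below 2³¹; `quantile(type = 7)` for
percentile intervals; `nnet` initialization is seeded so training is
bit-reproducible.

# Known limitations

* The exact point-selection rules of the original clinical heuristic are
  not fully recoverable from the published descriptions (treatment of
  non-monotonic flanks, multiple significant runs); our reconstruction is
  one consistent reading, with each step a named configuration point.
* The default conversion factor is a placeholder; absolute acuity values
  are only as good as that calibration.
* The ML module's contract is behavioral; it does not reproduce any
  previously published network's weights or training data.
* EDF input is not currently supported; recordings enter as plain tabular
  text (CSV with a JSON sidecar).
* The 2×2 interaction (vision × occlusion) is not tested; like the study
  design it serves, the package analyzes the occlusion contrast within
  each vision level separately.
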