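---
title: "Simulating and analysing phonological oddball MEG sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing phonological oddball MEG sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddballmeg)
```

## The scientific problem

In a passive auditory oddball paradigm a frequent "standard" sound is
interleaved with rare "deviant" sounds. The brain's differential response to
deviants — a mismatch negativity (N200-window) followed, for salient or
meaningful deviants, by a P300-window response — indexes pre-attentive
change detection and later attentional/semantic processing. When the
standard is a nonword and the deviants are a real word and a matched
nonword, the *word contrast* (word deviant minus standard) isolates
sensitivity to word-like phonological forms.

`oddballmeg` implements, end to end, the statistical pipeline such studies
use on children's magnetoencephalography (MEG) data:

1. **Session and cohort simulation** with known planted structure, so every
   downstream stage is testable without access to raw recordings;
2. **Evoked and contrast fields**: per-condition trial averages and
   deviant-minus-standard difference fields per subject;
3. **Behavioral reduction**: PCA with varimax rotation and Horn's parallel
   analysis turn a correlated test battery into a few orthogonal factor
   scores; socioeconomic covariates are built from OECD-equivalized
   household income and a 10-rung subjective-status ladder;
4. **Mass-univariate GLM**: ordinary least squares at every
   (sensor, timepoint) of the word contrast, with an intercept plus seven
   z-scored covariates;
5. **Cluster-based permutation inference**: spatio-temporal clusters over
   the sensor-adjacency × time grid, tested against max-statistic Monte
   Carlo nulls from sign flips (contrast test) or per-regressor shuffles
   (GLM test), which controls the family-wise error rate.

## The stimulus protocol

The default `oddball_protocol()` encodes the reference session: 1200 trials
at a 6:1:1 standard:word:nonword ratio (900/150/150), between 2 and 5
standards separating successive deviants, a 10-standard lead-in so
listeners habituate, and an 800 ms inter-stimulus interval (offset to
onset). Stimulus duration is not part of those constraints; we use 400 ms,
a realistic duration for a spoken consonant–vowel–consonant word, giving an
onset-to-onset interval of 1200 ms. The lead-in counts toward the 900
standards, since 900 + 300 deviants equals the stated 1200 total.

Gap sampling must satisfy the exact counts *and* the gap bounds
simultaneously, so `simulate_trial_sequence()` first draws gaps uniformly
from the allowed range and then repairs them by ±1 adjustments on randomly
chosen gaps until the standard count is exact. Deviant subtypes are
interleaved uniformly at random subject to the exact 150/150 split; nothing
constrains subtype alternation.

```{r protocol}
session <- simulate_trial_sequence(oddball_protocol(), seed = 1)
table(session$label)
range(inter_deviant_gaps(session))
```

## What the generator emulates — and what it does not

`simulate_cohort()` draws a socioeconomically diverse child cohort:
log-normal household income moment-matched to a mean of £24,313 and SD of
£12,261 per year (the distribution family is our choice; only the moments
are given), a subjective-SES ladder rating produced by cutting an
income-correlated latent normal (correlation 0.5 by default) into
population deciles, ages uniform over roughly 7–12.75 years, and household
compositions (1–2 adults, 1–3 children) that feed the OECD-modified
equivalence scale (0.67 / 0.33 / 0.20, couple-normalized, as in UK
households-below-average-income statistics — the scale is configurable).
The eight-measure behavioral battery follows a planted three-factor simple
structure (loadings 0.65–0.75) plus unique noise, rescaled to an
age-standardized-like mean 100 / SD 15 metric; the generating latents and
loadings are attached for recovery tests.

`simulate_evoked_dataset()` applies a separable forward model: each evoked
component is a spatial weight map (a Gaussian bump on the helmet plane)
times a raised-cosine (Hanning) temporal kernel over its window — the
waveform shape is our choice; nothing in the target literature fixes it —
scaled by `base + sum(beta_k * z(covariate_k))` per subject. The default
spec plants an early auditory response (~80–160 ms, all conditions),
lateralized N200-window mismatch components (~170–240 ms) and later
P300-window components (~320–400 ms) for the deviants, with the word
deviant's late component modulated by subjective SES. Noise is Gaussian,
spatially mixed with neighbouring sensors and temporally smoothed (so it is
band-limited like filtered sensor noise), with the evoked-level SD scaled
by `1/sqrt(n_trials)` of each condition — standards, averaged over 900
trials, are cleaner than deviants averaged over 150.

What the generator does *not* emulate: real sensor physics (no dipoles,
lead fields, or planar-gradiometer geometry), heartbeat/blink artifacts,
head movement, trial-to-trial latency jitter, or non-Gaussian noise.
Passing tests therefore demonstrate that the *statistical machinery* is
correct and calibrated under the stated conditions, not that real MEG data
would satisfy those conditions. Epochs run −200 to +1000 ms at 250 Hz by
default (the sampling grid is our choice; 250 Hz keeps arrays small while
resolving the component windows); tests and examples often use 50–100 Hz
grids for speed — the methods are sampling-rate agnostic.

## Behavioral reduction and SES covariates

Regressor standardization uses the population-SD convention (divide by
*n*) throughout; this only matters for exact example values and is fixed
package-wide. `fit_factor_model()` drops near-constant columns (≥ 95%
identical values) with a warning — the ceiling-effect situation that makes
an alliteration-style measure uninformative in this age range — then
z-scores, eigendecomposes the correlation matrix, retains components (by
parallel analysis against the 95th percentile of same-shape Gaussian
eigenvalues, or a fixed count: the pipeline fixes 3 cognitive factors and 1
attainment factor, the plausible-factor choice for this battery), rotates
with varimax (Kaiser row normalization by default) and computes regression
(Thurstone) factor scores — the scoring method is our choice where the
convention is unstated.

One numerical subtlety: the planar-rotation varimax iteration can stall on
a zero-gradient saddle when the unrotated loadings are exactly symmetric
(tied eigenvalues of a noiseless battery). `rotate_varimax()` therefore
restarts from a small fixed set of orthogonal rotations and keeps the
solution with the largest criterion; the restarts are deterministic, so
results are reproducible. Tests verify the converged criterion against a
brute-force grid search over the rotation angle in the two-factor case, and
that 50 random orthogonal starts reach the same criterion.

## The mass GLM

`build_design_matrix()` prepends an all-ones intercept (the group-mean
regressor — the only reading of a "constant regressor of value 1"
consistent with an n × 8 matrix holding seven named covariates) and
z-scores every covariate. The number of regressors is always derived from
the design, never hard-coded. Age enters as an ordinary covariate because
the battery scores are age-standardized upstream. `fit_ols()` solves every
(sensor, timepoint) in a single QR factorization; degrees of freedom are
`n − p` with no spatial smoothing or variance regularization. Property
tests check the vectorized solve against a per-point normal-equation
oracle to 1e−10 and the null t map against the Student t(n − p)
distribution.

## Cluster inference

Both engines share the same construction. Clusters are connected components
of `{|t| > threshold}` on the sensor-adjacency × time grid (neighbours:
same timepoint and spatially adjacent sensors, or same sensor and adjacent
timepoints), formed separately for positive and negative excursions; the
cluster statistic is the signed mean of member t values (`sum_t` cluster
mass is available as a cross-check option). The reference thresholds are
t = 4 for the word-vs-nonword contrast test and 2.8 for the GLM tests;
both are far above the analytic two-sided critical value
`critical_t(0.05, 70)` ≈ 2, and the threshold choice only trades cluster
interpretability against sensitivity since it is repeated in every
permutation.

The null distribution records the **maximum** |cluster statistic| per
permutation — the standard construction that actually controls family-wise
error and matches 95th-percentile language; permutations with no
supra-threshold cluster contribute 0, so p values are always well defined.
Monte Carlo p uses the +1 correction, `(1 + #{null ≥ obs}) / (1 + B)`,
avoiding p = 0. The repeated-measures contrast test is realized as a
one-sample sign-flip test on per-subject difference fields, the standard
resampling scheme for paired designs. The regressor-shuffle test permutes
only the target column's rows, holding all covariates fixed, and refits the
full model per permutation. Cluster onset and temporal extent are reported
descriptively only — the permutation scheme tests the statistic, not the
location — with extent `(offset − onset)` sample steps and a floor of one
step for single-sample clusters.

```{r cluster-demo}
sensors <- build_sensor_array(20, layout = "grid")
cohort <- simulate_cohort(40, seed = 2)
evoked <- simulate_evoked_dataset(
  cohort, oddball_protocol(), sensors,
  default_effect_spec(sensors), sfreq = 50, seed = 3
)
mismatch <- contrast_field(evoked, "word_vs_nonword")
test <- signflip_contrast_test(
  mismatch, sensors, cluster_config(4, n_permutations = 500, seed = 4)
)
cluster_table(test)
```

## Calibration choices and problem sizes

The planted subjective-SES slope on the late word component defaults to 25
field-strength units per SD, against a trial-level noise SD of 150 (about
12 units at the deviant evoked level). This was set analytically so that
the 40-subject recovery condition has an expected peak regressor |t| near
9: under a mean-t cluster statistic the max-statistic null is dominated by
single-point noise excursions (|t| ≈ 4 on a 1000-point grid at 32 degrees
of freedom), so a reliably detectable cluster needs member t values well
above that — an honest property of mean-t cluster inference worth knowing
when planning real studies.

Simulation-based checks run at reduced scale, chosen so the full suite
completes on a laptop: family-wise error calibration uses 200 null datasets
of 30 subjects on a 20-sensor × 50-timepoint grid with 500 permutations;
recovery uses 50 runs of 40 subjects at a 50 Hz grid. The reference-scale
configuration (71 subjects, 102 sensors, 250 Hz, 5000 permutations per
regressor) runs through the identical code path via `run_full_pipeline()`.

## Known limitations

* Only orthogonal (varimax) rotation is implemented — no promax, no
  maximum-likelihood factor analysis, no missing-data imputation beyond row
  exclusion.
* No threshold-free cluster enhancement, cluster-extent inference or FDR
  alternative; the max-statistic construction is the only correction.
* Epochs are time-locked to stimulus onset; the point at which the deviant
  becomes acoustically distinguishable (the final phoneme) is carried as
  metadata, not as an alternative time lock.
* Real-data preprocessing (signal-space separation, ICA denoising,
  filtering) is out of scope: synthetic epochs are generated band-limited,
  so no filter stage exists.
* Arrays are written as `.rds` plus long-format TSV/JSON sidecars; no HDF5
  binding is required at run time.
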