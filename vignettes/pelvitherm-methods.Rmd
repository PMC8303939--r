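---
title: "PRFS thermometry benchmarking and imaging-based session selection: methods"
author: "pelvitherm"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelvitherm)
```

## The problem

During deep pelvic hyperthermia, tissue is held at 40--44 °C for about
90 minutes, and treatment quality depends on knowing the temperature
distribution. Proton resonance frequency shift (PRFS) MR thermometry
maps temperature *change* non-invasively: the water-proton resonance
varies linearly with temperature, so the phase difference between a
gradient-echo scan at time $n$ and a pre-treatment baseline encodes
$\Delta T$:

$$\Delta T(n) = \frac{\phi_n - \phi_{00}}{\gamma\,\alpha\,B_0\,TE}$$

with $\gamma = 267.5\times10^6$ rad/T·s, the PRF change coefficient
$\alpha$, field strength $B_0 = 1.5$ T and echo time $TE = 19.1$ ms.
The method assumes a stationary anatomy: anything else that shifts
phase between scans — scanner $B_0$ drift, susceptibility changes from
gastrointestinal air that moves between scans — masquerades as
temperature. In the pelvis, moving bowel air is the dominant confounder.

The package implements the full evaluation chain: reconstruct
temperature maps, suppress the confounders, benchmark the result
against intraluminal probes (the clinical gold standard: thermistor
probes in catheters in the bladder, rectum and vagina, mapped every
5 min in 1 cm steps), and ask whether cheap pre-treatment imaging
features — above all the Jaccard overlap of the air masks of two
baseline scans taken ~97 s apart — predict which sessions will have
trustworthy thermometry.

A note on $\alpha$: the package defaults to $-0.001$ ppm/°C, the value
used by the clinical processing chain this package models. The
conventional literature value is $-0.01$ ppm/°C; it is one argument
away (`prfs_constants(alpha_ppm_per_C = -0.01)`), and every stage is
linear in $1/\alpha$, so the choice rescales temperatures without
changing any of the selection logic. With the small default, the phase
increment is only $-7.66\times10^{-3}$ rad/°C, which makes the
reconstruction very sensitive to phase noise — a property the noise
defaults below respect.

## Processing chain

`reconstruct_session()` applies five stages, each gated so it can only
run once and in order:

1. **Phase-difference maps** (`session_delta_t`): the wrapped
   difference $\angle e^{i(\phi_n-\phi_{00})}$ divided by
   $\gamma\alpha B_0 TE$. Wrapping matters only when drift or
   artifacts push the raw difference across $\pm\pi$, but the contract
   is wrap-safe regardless. The second baseline is never used as a
   reference; it exists to measure inter-baseline air motion.
2. **Low-SNR masking** (`mask_low_snr`): a voxel deviating more than
   3 °C from the mean of its eight in-plane neighbours (the voxel
   itself excluded, so a lone spike is detectable; border voxels use
   the neighbours that exist) is invalidated before it can pollute the
   drift fit.
3. **Fat-referenced drift correction** (`correct_drift`): fat
   undergoes no PRFS shift, so apparent temperature change in fat is
   $B_0$ drift. Per scan and per slice, a 2D polynomial of total
   degree ≤ 2 is least-squares fitted to the valid fat voxels and
   subtracted from the slice. Degree 2 captures smooth field drift;
   slices with too few fat voxels fall back to a lower order with a
   warning, and slices with none are left uncorrected and flagged.
   Masked voxels are never interpolated — they are simply excluded
   from fitting and from every ROI mean.
4. **Outlier exclusion** (`apply_exclusion` /
   `optimize_exclusion_threshold`): voxels with $|\Delta T| > p$ are
   treated as corrupted. The default $p = 7$ °C is the clinical
   optimum; with probe traces available the threshold can be
   re-derived by a 0.1 °C grid search on $[0, 20]$ °C minimising the
   mean absolute disagreement between surviving-voxel ROI means and
   the aligned probe means (smallest $p$ on ties, for determinism).
   The filter acts on absolute values: heating and artifact errors
   both carry signs.
5. **ROI averaging** (`roi_mean_series`): per probe location and scan,
   the mean over valid ROI voxels pooled across the location's slices.
   Empty ROIs yield `NA`, never a fabricated number.

ROIs are circles of diameter 1.37 cm (area 1.47 cm²) centred on the
probe track in every slice the track crosses (2--8 slices). A voxel
belongs to the ROI iff its centre lies in the circle; this is exact
and grid-independent, at the cost of a discretisation error that is
within one voxel of the analytic area at in-plane grids of 96 and
finer, and within 5% at the clinical 256 grid.

**Probe alignment.** Probes map every 5 minutes; a scan lasts 83 s.
For each scan the probe cycle whose start lies nearest the scan
midpoint (and within 150 s) provides the reference, and the location's
reading is the mean over its mapped positions. The synthetic scan
schedule starts scans at $600n - 41.5$ s so midpoints land exactly on
probe cycles; real schedules simply incur the ≤150 s interpolation
error.

## Benchmarking metrics and selection

Per session and location, against the aligned probe series:
accuracy = mean |MR − probe| (°C); temporal precision = sample
standard deviation of the ROI means over time; bias = signed mean
difference (negative ⇒ MR underestimates). Accuracy ≥ |bias| always.
Missing pairs are dropped pairwise. A session is *acceptable* when the
mean of its per-location accuracies is ≤ 1 °C (inclusive). Locations
are compared by classical one-way ANOVA (`compare_locations`), with a
degeneracy flag when the within-group variance vanishes.

Four pre-treatment imaging features are evaluated as predictors of
acceptability: the Jaccard coefficient $J(A,B) = |A\cap B|/|A\cup B|$
of the two baseline air masks (1 = no motion; defined as 1 when both
masks are empty), the air volume of the first baseline, the fat
volume, and the mean minimum distance between air and the probe ROIs
over ROI-bearing slices (slices without air contribute the in-plane
FOV diagonal as a cap, so air-free sessions score as "far" instead of
dropping out of the ROC input — a declared convention).

ROC analysis uses thresholds at the observed feature values plus
$\pm\infty$ sentinels, inclusive on the positive side, so the reported
optimal cut-off (the point nearest (FPR, TPR) = (0, 1); ties towards
lower FPR) is always an attainable data value. Orientations follow the
physical argument: higher Jaccard and larger air distance favour
reliability, larger air and fat volumes disfavour it; all are
configurable. The trapezoidal AUC equals the Mann–Whitney concordance
with ties counted ½. Because the study that motivated this analysis
cites no specific CI/p-value method, inference is by resampling: a
stratified bootstrap percentile 95% CI and a label-permutation p-value
for AUC = 0.5 (two-sided by the symmetry of the permutation null);
this is a declared substitute, not a reproduction of any specific
parametric formula. Selection (`select_sessions`) is inclusive:
Jaccard ≥ cut-off (0.91 in the clinical study).

### Aggregation conventions of the summary table

`summarize_cohort()` and `reproduce_table2_arithmetic()` aggregate
per-location means into overall values, threshold deviations and
improvement percentages. Where several defensible conventions exist,
the package fixes these: the overall value of a metric is the mean of
its three per-location means, quoted after one-decimal rounding;
deviations compare the rounded overall against the thresholds (1 °C
accuracy, 1 °C precision, ±0.5 °C bias, absolute value for bias); the
accuracy improvement is computed from the rounded overalls (falling
back to unrounded values if rounding collapses the denominator), while
precision and bias improvements are the mean of per-location relative
improvements (bias on absolute values; locations with a zero
denominator are dropped, and an all-zero input flags `NA`). On the
published clinical per-location means these conventions return the
published 50% / 26% / 80% improvements exactly:

```{r table2}
t2 <- reproduce_table2_arithmetic(clinical_table2())
t2$overall
t2$improvement
```

One published cell is not derivable from the published per-location
means under any consistent rule we found: the bias deviation of the
selected dataset prints −0.3 °C, while |overall| − 0.5 gives −0.2 °C
from the printed means (−0.4, −0.4, 0.0). The package reports the
computed −0.2.

## The synthetic-session generator

No patient data are available, so every downstream stage is exercised
on synthetic sessions whose ground truth is known exactly.

* **Anatomy** (`generate_anatomy`): an elliptical body (semi-axes
  0.42/0.34 of the FOV), a subcutaneous fat ring (default 1.5 cm),
  three probe tracks along the slice axis at fixed in-plane stations,
  and an ellipsoidal air pocket. Air motion is controlled exactly: the
  second baseline's mask removes $m$ voxels from one flank and
  accretes $m$ on the other, giving $J = (V-m)/(V+m)$; $m$ is chosen
  so the achieved $1-J$ is within ±0.05 of the request (exactly 1 or 0
  at the boundaries). The voxel count of the pocket matches the
  requested volume to one voxel by construction.
* **Ground truth** (`generate_truth`): a Gaussian heating focus
  (default peak 4 °C, σ 3 cm, matching the 2--3 °C probe-level
  changes reported clinically) with a saturating-exponential ramp
  (default 15 min) switched on after the second baseline; truth is
  identically zero at both baselines, and fat is kept thermally inert
  so the drift reference is valid by construction.
* **Encoding** (`encode_session`): phase = baseline + $\gamma\alpha
  B_0 TE\,\Delta T$ + drift + artifact + white noise, wrapped to
  $(-\pi,\pi]$. Drift is an in-plane quadratic accumulating linearly
  in time (default scale 0.05 rad/h ≈ 6.5 apparent °C/h at the
  default $\alpha$ — deliberately large so correction is genuinely
  exercised). The susceptibility artifact is a dipole-like pattern
  (weight 2 inside air, decaying as $e^{-d/2}$ over a four-voxel
  shell, modulated by $\cos 2\theta$) whose per-scan amplitude is
  `air_artifact_rad` (0.5 rad) × $(1-J)$ × a standard-normal draw:
  any monotone link between air motion and phase error serves the
  selection experiment, and this one reproduces the clinical error
  regime (~1--2 °C session accuracy at moderate motion, crossing the
  1 °C acceptability boundary near a motion fraction of ~0.2).
* **Probes** (`sample_probe_readings`): truth sampled at the track
  voxels every 5 min with 0.05 °C reading noise.

What the generator does *not* emulate: intra-scan motion blur,
respiration and organ deformation, coil/B1 effects, realistic k-space
sampling, partial-volume fat, or probe self-heating. Passing tests
therefore demonstrate that the chain recovers known truth under the
modelled confounders, not that clinical accuracy would match these
numbers.

## Cohort experiments and problem sizes

`run_cohort_experiment()` chains everything from one config
(`cohort_config()`, YAML round-trippable; all randomness derives from
one root seed by seed splitting). Defaults: 30 sessions on a
96 × 96 × 9 grid (the coarsest grid whose ROI rasterisation stays
within one voxel of the clinical ROI area; in-plane voxel 0.52 cm),
motion fractions evenly graded over 0--0.5 with seeded jitter, air
volume U(80, 250) mL, fat ring U(1.0, 2.2) cm, nine treatment scans,
the fixed clinical 7 °C exclusion threshold, and selection by the
cohort's own ROC-derived Jaccard cut-off. A 30-session cohort runs in
well under a minute; the package's own checks run twenty such cohorts
to establish that Jaccard selection improves overall accuracy and that
the Jaccard AUC exceeds the fat-volume AUC across seeds. The
single-session round-trip check uses 128 × 128 × 15 with eleven scans;
the clinical 256 × 256 × 25 geometry is supported but not the test
default.

```{r cohort, eval = FALSE}
exp <- run_cohort_experiment(cohort_config(seed = 7))
glance(exp)
autoplot(exp$summary)
autoplot(exp$roc$results$jaccard)
```

## Numerical choices and degenerate inputs

* Phases are stored wrapped in $(-\pi,\pi]$; all differences are taken
  through the wrapped angle, so decoding is exact to ~1e-13 °C on
  confounder-free sessions.
* The drift fit uses a QR solve; rank-deficient fat supports drop the
  unidentifiable coefficients (set to zero) rather than failing.
* Grid search for the exclusion threshold is vectorised by sorting ROI
  voxels by $|\Delta T|$ and using cumulative sums, and returns the
  smallest grid point attaining the minimum; a candidate that empties
  an ROI skips that term, and a candidate that empties everything maps
  to $G = \infty$.
* ROC ties are counted ½ in the AUC; the optimal cut-off prefers lower
  FPR and never returns a $\pm\infty$ sentinel when a finite threshold
  ties it.
* Degenerate inputs flag rather than fabricate: empty ROI means are
  `NA`, precision of fewer than two points is `NA`, single-class label
  sets are a hard error for ROC, ANOVA with zero within-group variance
  carries a `degenerate` flag, classes smaller than three flag a
  widened (full) bootstrap CI.

## Known limitations

The synthetic anatomy is deliberately schematic (one air pocket, fixed
track stations, elliptical body), so feature distributions — notably
the minimum air-to-ROI distance, whose no-air cap dominates in many
slices — need not mirror clinical ones; in synthetic cohorts the
distance feature can appear predictive because it co-varies with the
single pocket's geometry, whereas the clinical study found it near
random. The drift model is exactly representable by the correction
polynomial, which makes criterion-style recovery checks sharp but
optimistic about real scanner drift. Inference for the AUC is
resampling-based and will differ in small samples from parametric
CIs. The exclusion-threshold optimiser shares the probes with the
evaluation, as in the clinical processing; it is a calibration, not an
independent validation.
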