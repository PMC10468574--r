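---
title: "Dual GLM/ICA analysis of single-subject task fMRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual GLM/ICA analysis of single-subject task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fmridual)
```

## The problem

Presurgical language mapping asks a single question of a single scan: which
brain regions does this patient use for language? The standard analysis is a
voxel-wise general linear model (GLM) against the task time course. It is
reliable when the subject cooperates, but it inherits every assumption baked
into the design matrix: that the subject performed the task on schedule, that
head motion is well captured by the realignment parameters, and that those
parameters are not themselves correlated with the task. Spatial independent
component analysis (ICA) makes none of these assumptions — it decomposes the
scan into spatially independent sources and lets the analyst pick the
language component afterwards — at the price of an extra selection step and
occasional failures of its own (an activation split across components, or
merged with an artifact).

`fmridual` implements both routes end to end, pushes both statistic maps
through one shared thresholding scheme, and scores the resulting maps
against known ground truth with a 0–5 reliability rubric. Because real
clinical scans are not available, the package ships a block-design BOLD
phantom generator whose failure modes (task-correlated motion, lesion signal
dropout, non-compliance) are planted deliberately, so every downstream claim
is verifiable.

## The GLM route

Each voxel's series $Y$ is modelled as $Y = X\beta + e$. The design has the
HRF-convolved task boxcar as its regressor of interest, its temporal
derivative (absorbing small HRF lag errors) and the six motion parameters as
nuisance regressors, plus an explicit intercept; motion-parameter
derivatives are deliberately excluded. The HRF is a single gamma density
with mean lag 6 s and standard deviation 3 s, sampled on the TR grid and
normalised to unit sum so that the task coefficient stays in
percent-signal-change units. "Mean lag" is read as the distribution mean
(moment matching: shape $(6/3)^2 = 4$, scale $3^2/6 = 1.5$ s), not the mode;
the alternative reading would shift the kernel by about 1.5 s and is
absorbed in practice by the derivative regressor.

Errors are not white: BOLD noise is temporally autocorrelated. The fit is
therefore a two-pass scheme: ordinary least squares, then a voxel-wise AR(1)
coefficient from the residuals (lag-1 autocorrelation with the standard
$(1+3\rho)/n$ small-sample correction, spatially smoothed at 8 mm FWHM to
suppress estimation noise, clipped to $\pm 0.95$), then one generalised
least-squares refit on AR(1)-whitened data and design. There is no further
iteration; the scheme is bounded-time and, on AR(1) nulls at the study's
series length, leaves the whitened z-map standard deviation within a few
percent of 1 (the test suite asserts $1 \pm 0.05$ and tail calibration at
$z = 2.3$). Voxels are grouped by their coefficient rounded to 0.01 so the
whitened design and its Gram inverse are computed once per group; the
rounding error is far below the AR estimation error, and the $\rho = 0$
group reduces exactly to OLS. Each voxel keeps its own error variance.
The task-contrast statistic is converted from $t$ (at $t - r$ degrees of
freedom, uncorrected for AR estimation — a documented approximation) to a
z-score by tail-probability matching on the log scale.

## The PICA route

The probabilistic ICA model is $X = AS + \eta$ with Gaussian noise. Four
steps:

1. **Variance normalisation.** Each voxel's series is demeaned and divided
   by an estimate of its noise standard deviation — the residual std after
   projecting out the top `k_noise = 20` principal components (which carry
   the structured signal). The mean and scale are stored, so the transform
   undoes exactly.
2. **Model order.** The number of retained components $q$ maximises the
   Laplace approximation to the Bayesian evidence of a probabilistic-PCA
   model over the eigenspectrum of the time-by-time covariance (Minka's
   approximation). Two practical amendments matter on real pipeline data:
   eigenvalues that are numerically zero (the null space created by
   high-pass filtering and demeaning) are excluded before model comparison,
   and the sample count entering the evidence is the number of *effectively
   independent* voxels — the voxel count divided by the smoothness-kernel
   volume in voxels — because spatial smoothing makes neighbouring voxels
   dependent and would otherwise inflate the order severely. On spatially
   white phantoms the raw voxel count is used and the estimator recovers
   planted orders essentially exactly. The pipeline additionally caps
   $q \le 40$.
3. **Unmixing.** After PCA whitening to $q$ dimensions, a symmetric
   fixed-point iteration maximises the log-cosh negentropy proxy of the
   spatial maps, with symmetric decorrelation each step, 3 random restarts
   (best contrast value kept) and a convergence tolerance of $10^{-6}$ on
   the unmixing rotation. Non-convergence raises an error by default
   (the pipeline downgrades it to a warning and keeps the best iterate);
   data whose components are indistinguishable from Gaussian noise are
   flagged as unidentifiable.
4. **Component z-maps.** Each raw map, restored to original intensity
   units, is divided by the voxel-wise standard deviation of the estimated
   noise $\eta$ (the part of the data outside the retained subspace, with
   $p - q$ denominator degrees of freedom). No mixture model is fitted to
   the component histograms: plain division is the stated model, and on
   noise-only components it yields maps that behave like standard normal
   fields ($E|z| \approx \sqrt{2/\pi}$, asserted in the tests).

**Task-component selection.** The study's experts selected the language
component by its anatomical plausibility and similarity to the GLM map; an
automated surrogate replaces them here: each component scores
$0.6\,\mathrm{corr}(|z_c|, |z_{GLM}|) + 0.4\,|\mathrm{corr}(A_{\cdot c},
x_{task})|$, the maximum wins (ties to the lower index), and components
scoring at least 75% of the maximum whose suprathreshold maps are pairwise
disjoint (Dice < 0.2 at $z = 2.3$) are reported as a split set — covering
the scans where ICA divides the activation across components. The weights
are explicit configuration, not inferred expert intent.

## Shared preprocessing and thresholding

Both routes consume identical data: 3 leading and 4 trailing volumes
trimmed, 4 mm FWHM isotropic Gaussian smoothing (separable, zero-padded
boundaries), a 50 s high-pass implemented as residualisation against an
orthonormal DCT basis (all components with period above the cutoff; the
temporal mean is retained because the PICA variance normalisation needs it
separately; the operator is a projection, hence idempotent), and an
intensity-threshold brain mask (98th-percentile robust maximum, fraction
0.1). The task regressor is filtered with the same DCT operator as the
data; the motion regressors are not — a deliberate asymmetry that mirrors
common practice and is precisely what makes task-correlated motion
hazardous for the GLM.

Thresholding is dual: four voxel-wise z cut-offs {2.3, 2.6, 2.9, 3.1}
combined with a cluster-extent criterion at $p < 0.05$. The extent
threshold comes from a Monte-Carlo null: Gaussian fields matched to the
smoothness estimated from the standardised whitened GLM residuals
(per-axis FWHM from the variance of spatial finite differences,
$\mathrm{FWHM} = \sqrt{4\ln 2/\mathrm{var}(d)}$ voxels), simulated on the
analysis mask, thresholded, and the 95th percentile of the maximum cluster
extent plus one voxel taken as $k^*$. Monte Carlo was chosen over
closed-form Gaussian-random-field theory because the closed forms are
inaccurate at 4 mm smoothness on 2 mm voxels, and a simulated null is
directly testable (the suite verifies family-wise error within
[0.02, 0.10] at nominal 0.05). Clusters use 26-connectivity; thresholding
is positive-tail by default (activation mapping); both are configuration,
as the one-sided/two-sided question and the connectivity rule are genuinely
open choices. A cohort run caches the null by smoothness rounded to
0.5 mm, since scans of one cohort share their smoothness to well within
that resolution.

## The reliability rubric

The study's experts scored each chosen map 0–5. The package replaces them
with an overlap-based surrogate against the planted truth — declaredly a
surrogate, not a claim of equivalence:

* a planted region is **visible** when the map covers ≥ 10% of it, and
  covered to a **satisfactory extent** at ≥ 50%;
* a map cluster is a **noise cluster** when ≤ 10% of its voxels lie in the
  truth, and **interfering** when it comes within 10 mm of a truth voxel;
* scores: 0 — no cluster or no visible region; 5 — all six regions
  satisfactory, no noise clusters; 4 — all six visible, no noise clusters;
  3 — at least half visible, no interfering noise; 1 — interfering noise
  clusters outnumber the visible regions; 2 — everything else (few regions
  and/or interfering noise). The 1-vs-2 boundary is the one genuinely
  qualitative line in the original scale; "interfering noise dominates" is
  the coded reading.

The best of the four candidate maps is reported per method, ties broken
toward the stricter threshold (the cleaner map). "Reliable" means score
≥ 3 throughout, which drives the complementarity table (scans where exactly
one method is reliable, and the conditional score histograms).

## What the phantom emulates — and what it does not

One scan is `baseline + activations + artifacts + drift + AR(1) noise` on a
32 × 32 × 24 grid of 2 mm voxels (an ellipsoidal "brain" of ≈ 7000 voxels;
desk-scale, preserving multi-region geometry rather than matching the full
acquisition matrix), 177 volumes at TR 1.7 s with six 24 s task / 24 s
control blocks, 3 dummy and 4 tail volumes. Six spherical
"language-critical" regions (frontal, temporal, parietal, occipital,
median, deep locations) carry HRF-convolved boxcar time courses at 1.2%
signal change over a baseline of 1000 — the standard BOLD
percent-signal-change convention, which keeps amplitudes interpretable.
Noise is AR(1) ($\rho = 0.3$, 1% marginal std), with two slow cosine drift
components (128 s and 211 s periods, 0.3%/0.2%). The boxcar is sampled at
volume midpoints — symmetric and TR-independent.

Three failure archetypes mirror the clinical cohort:

* **Task-correlated motion** (the decisive one): the first translation
  column of the motion trace acquires a low-pass-filtered task boxcar of
  1.2 mm (heads settle sluggishly), and an artifact source confined to the
  brain rim follows that motion column at 25 intensity units/mm. Because
  the artifact's time course lies in the span of the (unfiltered) motion
  regressors while the data are high-pass filtered, and because the motion
  column is collinear with the task regressor, the GLM task map acquires
  rim bias and variance inflation; spatial ICA, which never sees the
  design, isolates the rim source in its own component. This reproduces
  the qualitative mechanism by which the two methods diverge, without
  implementing image re-slicing.
* **Lesion dropout**: a spherical lesion engulfing the temporal region
  removes its planted signal entirely (complete neurovascular-uncoupling
  archetype), capping both methods at score 3 on those scans.
* **Non-compliance**: zero planted amplitude; both methods must score 0.

Cohort archetype rates (30% task-correlated motion in patient groups for
the analysis cohort, amplitude scales 1/0.85/0.75, motion random-walk steps
0.02/0.05/0.08 mm for controls/group1/group2) are free parameters of the
generator — the study quantifies neither patient motion nor compliance —
fixed once here and recorded per manifest row.

What the phantom does **not** model: k-space physics, susceptibility and B0
inhomogeneity, slice timing, spin-history effects, physiological
(cardiac/respiratory) noise, true image motion requiring re-slicing, and
anatomical variability. Passing tests therefore demonstrate internal
correctness and the stated mechanism of divergence, not clinical
performance on real scanner data.

## Numerical choices and degenerate inputs

* Smoothing uses explicit per-axis convolution matrices; zero-padding means
  boundary rows sum to slightly under one (no renormalisation), which is
  visible in mass-preservation tests only at the edge.
* Constant voxels: excluded (unit scale) in variance normalisation; AR
  coefficients of degenerate residuals clip at the ±0.95 bound; zero-variance
  voxels get z = 0 and are counted in a flag attribute rather than producing
  NaNs.
* All randomness (noise, ICA restarts, Monte-Carlo nulls, manifest
  archetypes) derives from integer seeds through one stable hash, so any
  scan or cohort is reproducible independent of execution order.
* Problem sizes in the shipped tests and scripts — 5000-voxel null
  calibrations, 20-replicate order-recovery runs, 200-field family-wise
  error checks, a 30-scan analysis cohort — were chosen as the smallest
  sizes at which the Monte-Carlo standard errors are comfortably inside the
  asserted tolerances.

## Known limitations

* The GLM degrees of freedom ignore the AR-estimation cost; at 170 time
  points the effect is below a percent on the z-scale.
* The Laplace order selector's effective-sample correction uses the
  smoothness estimated from GLM residuals; on data smoothed far more than
  4 mm the order becomes conservative.
* The rubric's 10 mm interference radius and overlap fractions are blunt
  stand-ins for expert judgement; scores 1 and 2 in particular should not
  be over-interpreted individually (cohort-level contrasts are the
  supported use).
* Split-component handling reports the split set but thresholds only the
  primary component's map, as the original evaluation presented a single
  component per scan.
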