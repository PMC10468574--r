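# fmridual

Dual-route analysis of single-subject block-design task fMRI: a voxel-wise
general linear model (GLM) with AR(1) pre-whitening, and probabilistic
spatial independent component analysis (PICA) with automatic model-order
selection — both pushed through one shared thresholding scheme and scored
against known ground truth.

## Who this is for

Clinical task fMRI (e.g. presurgical language mapping) lives or dies on
single-scan reliability. The GLM is the standard route, but it fails in
characteristic ways when the subject moves with the task, performs it
erratically, or carries a lesion that decouples BOLD from neural activity.
Spatial ICA is design-free and can isolate such artifacts into their own
components — at the cost of an extra component-selection step and failure
modes of its own. This package implements both routes end to end on
simulated phantoms with planted truth, so the conditions under which each
route fails can be generated, measured and compared quantitatively.

## The models

**GLM route.** Per voxel, `Y = Xβ + e` with design columns: HRF-convolved
task boxcar (single gamma HRF, mean lag 6 s, std 3 s), its temporal
derivative, six motion parameters, intercept. Errors are AR(1); the fit is
OLS → residual lag-1 autocorrelation (bias-corrected, spatially smoothed) →
one generalised least-squares refit on whitened data (`WVW' = I`), with a
per-voxel error variance. The task contrast becomes a z-map by
tail-matching the t statistic.

**PICA route.** `X = AS + η`: voxel-wise variance normalisation
(`KΣK' = I`), model order `q` by the Laplace approximation to the Bayesian
evidence of the eigenspectrum, PCA reduction, fixed-point negentropy
(log-cosh) unmixing with symmetric decorrelation, and component z-maps by
dividing each raw map by the voxel-wise std of the estimated noise `η`.
The task component is selected automatically by similarity to the GLM map
(weight 0.6) plus task-regressor correlation of its time course (0.4),
with split-component detection.

**Shared tail.** Both z-maps are thresholded at voxel-wise
z ∈ {2.3, 2.6, 2.9, 3.1} combined with a cluster-extent criterion at
p < 0.05 from a smoothness-matched Monte-Carlo null, and the best of the
four candidate maps per method is scored 0–5 against the planted regions
(all-six-covered & clean = 5, down to empty = 0; "reliable" = score ≥ 3).

## Worked example

The numbered scripts under `analysis/` run the whole study in three stages
(`01_simulate_cohort.R`, `02_single_scan.R`, `03_cohort_compare.R`). The
decisive contrast is stage 2 — the same pipeline on a clean control scan
and on a task-correlated-motion scan:

```
== clean control scan (scan_001, control)
  GLM: median z in planted regions 11.62, background 0.48
  PICA: order 21, task component 1 (time-course corr 0.99)
 method chosen_voxel_z score regions_visible n_noise_clusters dice_truth
    glm            3.1     5               6                0  0.5437126
    ica            3.1     5               6                0  0.9016018

== task-correlated-motion scan (scan_011, group1)
  GLM: median z in planted regions 9.10, background 1.94
  PICA: order 18, task component 3 (time-course corr 0.94)
 method chosen_voxel_z score regions_visible n_noise_clusters dice_truth
    glm            3.1     2               6                1  0.1456529
    ica            3.1     5               6                0  0.8820755
```

On the clean scan both methods earn the top score. On the motion scan the
GLM map is contaminated — an interfering rim artifact cluster and a Dice
overlap with the truth of 0.15 — because the motion regressors are
collinear with the task regressor and the rim artifact leaks into the task
beta; the ICA route isolates the artifact in a separate component and still
delivers a clean map (score 5, Dice 0.88). Stage 3 aggregates a 30-scan
cohort:

```
    group method score        paired t-tests (ICA minus GLM):
  control    glm   5.0          control   n=10  mean diff +0.000  p=1.0000
   group1    glm   3.8          group1    n=10  mean diff +0.900  p=0.1708
   group2    glm   2.9          group2    n=10  mean diff +0.100  p=0.3434
  control    ica   5.0          patients  n=20  mean diff +0.500  p=0.1256
   group1    ica   4.7
   group2    ica   3.0        reliable (score >= 3): GLM 25/30, ICA 30/30,
                              combined 30/30
```

Controls are indistinguishable between methods; in the artifact-laden
patient groups ICA's mean score exceeds the GLM's; and combining both
methods never yields fewer reliable scans than either alone.

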