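---
title: "Stratifying premanifest Huntington's disease by functional connectivity density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying premanifest Huntington's disease by functional connectivity density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical trials in premanifest Huntington's disease (pre-HD) need to enrol
gene carriers who are actually deteriorating: testing an early intervention on
stable individuals dilutes any treatment effect. Longitudinal decline can be
measured directly from repeated cognitive and motor testing, but that takes
years. This package implements an analysis in which a *single* resting-state
fMRI visit is used to estimate the rate of ongoing cognitive/motor decline,
via voxel-level functional connectivity density (FCD) maps and site-robust
penalized classifiers, together with the reliability and confound analyses
that make such an estimate credible.

The cohort structure assumed throughout is that of a four-site observational
study of roughly 150 participants — about half pre-HD gene carriers and half
age- and sex-matched controls — with two imaging visits per subject and up to
seven yearly scores on ten cognitive/motor tasks. Because data of this kind
are not publicly downloadable, the package ships a seeded synthetic cohort
generator with the same statistical skeleton; every stage of the analysis is
exercised and tested against it.

## Functional connectivity density

For each subject-visit, the preprocessed BOLD series yields a voxel-level
graph: voxels are nodes, and a link joins two voxels whose Pearson
correlation strictly exceeds 0.7. A voxel's degree is its link count, and

FCD = log(degree + 1), normalized by the median across voxels.

Preprocessing applies exactly the computational steps that do not involve
registration: the first 5 frames are discarded; tCompCor identifies the top
2% of voxels by (detrended) temporal standard deviation as a noise mask and
regresses its top 5 principal component time courses out of every voxel; each
voxel is band-pass filtered at 0.01–0.16 Hz with a zero-phase order-4
Butterworth filter (the filter design is a package choice; the band is the
analysis's). Series are demeaned before filtering — DC lies in the stopband
anyway, and this eliminates the long edge transients the 0.01 Hz corner would
otherwise produce on ~480 s of data.

Numerical conventions, fixed here because downstream values depend on them:

* **Link rule**: strictly `> 0.7`; negative correlations never link.
* **Log base**: natural log. Because the map is divided by its median, the
  base only rescales the map globally; a subtraction variant
  (`normalization = "median-diff"`) is available behind a flag, and division
  is the default.
* **Median convention**: the order-statistic (type-1) median, so the baseline
  reference is an attained map value even for even voxel counts.
* **Degenerate maps**: a map with no links anywhere has median log-degree 0
  and cannot be median-normalized; this raises an explicit error rather than
  returning NaNs. Constant-variance voxels get degree 0 with a warning.
* **Smoothing** (univariate analyses only): 3-D Gaussian kernel with
  `sigma = FWHM / sqrt(8 ln 2)`, FWHM 2.5 voxels, with kernel weights
  renormalized over in-mask voxels so boundary values are not attenuated.
  Multivariate classifiers always use unsmoothed maps.
* **Motion QC**: a scan is excluded iff *more than* 10 frames have relative
  displacement above 0.6 mm (so exactly 10 is retained).

## Decline slopes and robust components

Each subject-task trajectory is summarized by its OLS slope over all
available visits — the simplest defensible measure given 2–7 noisy time
points; no mixed model is attempted. Tasks are oriented so that negative
slopes indicate decline. Healthy expectations are removed by fitting
`slope ~ age + sex` on controls only (age at the first functional image, sex
as a 0/1 indicator) and subtracting the fitted prediction, intercept
included, from everyone. Slopes are then divided by each task's interquartile
range (linear-interpolation, "type 7", quantiles) to make tasks
commensurate.

Decorrelated decline dimensions come from PCA of a robust covariance: the
minimum covariance determinant (MCD) over the default support
`h = ceiling((n + p + 1) / 2)`, searched exhaustively when `C(n, h) <= 1e5`
and otherwise by FAST-MCD (500 random elemental starts with concentration
steps), with the standard normal-consistency correction
`alpha / P(chisq_{p+2} <= q_alpha)` followed by the usual one-step
reweighting (points within the 0.975 chi-squared quantile of the corrected
robust distance, with the matching truncation factor). The reweighting
matters: the raw half-sample MCD is consistent but so inefficient that even
at n = 10,000 a single estimate sits several percent from the truth, while
the reweighted estimate is close to classical efficiency and keeps the
breakdown point. With `h = n` the estimator reduces exactly to the classical
covariance. Eigenvector signs are fixed by making
each component's largest-magnitude loading positive, so projections are
reproducible. Two fit populations are supported: controls plus carriers (for
visualizing group separation) and carriers only (for stratification); the
top 5 components are retained by default.

Note one geometric subtlety: PCA of a *robust* covariance decorrelates scores
with respect to that covariance, not with respect to the sample covariance of
the full fitting population; the two coincide in the classical limit
`h = n`, which is what the decorrelation property test pins down.

## Discretization and stratification models

For each decline measure (a task slope or PC projection), carriers are split
at the median ± half a robust SD, where the robust SD is the standard
deviation of the normal distribution with the observed IQR
(`IQR / 1.34898`). Values below the lower cutpoint are `fast` decliners,
above the upper are `slow`, and everything else — including exact boundary
ties — is `intermediate`. For normally distributed measures the cutpoints sit
at ±0.5 SD, splitting the population approximately into terciles
(31% / 38% / 31%).

`loso_stratify()` is the central fitting function. For each imaging site it
trains an elastic-net logistic classifier (`glmnet`) on the fast and slow
subgroups of all *other* sites, then scores every held-out subject —
including intermediates — by the affine decision value `w·x + b`. The
penalty pair is chosen by stratified internal 5-fold cross-validation
maximizing AUC over λ ∈ 10^{2..−3} (8 log-spaced values) and
α ∈ {0.1, 0.5, 0.9}, then refitted on the full training set. Validation
reports:

* per-site and site-averaged AUC on the extreme subgroups, plus a
  bootstrap-median AUC (within-site resampling of test subjects);
* the Spearman correlation between decision values and the continuous
  decline measure on *all* scored subjects, Fisher z-averaged across sites
  (the decision value is sign-oriented along the decline measure first, since
  the positive class is the low-value "fast" extreme);
* within-site permutation p-values with the add-one rule
  `(1 + #{null >= obs}) / (1 + n_perm)`, which never returns zero.

Every estimated preprocessing step — age/sex weights (learned from training
controls), ComBat site parameters, motion weights, atrophy residualization,
CAG standardization — is fitted on training-site rows only and applied to the
held-out site with the stored parameters. A dedicated test perturbs held-out
rows and asserts bit-identical fitted models.

Defaults use 1,000 permutations and bootstrap resamples; the reference
analysis scale of 1e5 is a configuration choice away.

## Reliability

Fingerprinting correlates each subject's baseline FCD map with every
subject's follow-up map and records the rank of the self-match (1 = best);
correlation ties are broken *against* the self-match. Chance level is `1/N`.

Classifier-outcome reliability uses the carrier-vs-control model: each
subject's two visits are scored by the model for which their site was held
out, thresholded at 0 (probability one-half; the analysis convention, since
no threshold is dictated by the science), labelled TN/FP/FN/TP, and
tabulated into a transition matrix `P(follow-up outcome | baseline outcome)`.
The null preserves each group's outcome mix by permuting follow-up outcomes
within group; diagonal cells get two-sided add-one permutation p-values.

## Confound controls

* **ComBat** (no covariates, so label information cannot leak): per-feature
  standardization by a grand mean and pooled scale, site location/scale
  estimation, and parametric empirical-Bayes shrinkage across features.
  The pooled scale uses the residual-df denominator `n − n_sites`, which
  makes the *un-shrunk* (`eb = FALSE`) location-scale adjustment exactly
  idempotent; with shrinkage, a second pass moves values only by the small
  shrinkage residual. A model fitted on training sites applies no adjustment
  to rows from unseen sites (no parameters exist for them); a `"global"`
  option harmonizes once before cross-validation instead.
* **Atrophy**: per voxel, FCD is regressed on grey-matter concentration
  across subjects and the prediction subtracted; constant-GMC voxels fall
  back to mean-centering with a warning. A GMC-only classifier reuses the
  identical LOSO machinery as a negative control.
* **Motion**: per feature, the linear weight of mean framewise displacement
  is learned from healthy controls and only the slope term
  `w · (fd − mean control fd)` is subtracted, preserving control means.
  None of the three corrections takes group labels as input.

## The synthetic cohort generator

`generate_cohort()` draws demographics matching the study conditions:
79 controls and 74 carriers over 4 sites, ages 49 ± 11 / 42 ± 10 (clipped to
18–65), CAG 43 ± 2, CAP = 100·age·(CAG − 35.5)/627, and a hidden
one-dimensional latent decline factor for carriers (mean 1, SD 0.6, weakly
tied to CAP with weight 0.3, mirroring the weak genetic association in this
population) that analysis stages never see. Mean framewise displacement is
log-normal and identically distributed in both groups.

Task scores follow
`baseline + (aging + sex + loading × latent) × years + noise`, with per-task
visit counts uniform on 2–7. Loadings are strongest for symbol-digit
substitution and cancelation (−0.55, −0.45 units/yr per latent unit) and
weakest for visuospatial tasks, with noise SD 0.35 — chosen so that
single-task slopes recover the latent factor at realistic fidelity
(correlation ≈ 0.8) rather than perfectly.

BOLD series (1,000 voxels on a 10×10×10 grid, 160 retained frames at
TR = 3 s, plus 5 unsteady leading frames) are linear latent mixtures:

* 20 background networks (loading 2) giving every map a stable degree median;
* a 60-voxel decline hub whose loadings `strength × latent × w_v`
  (`w_v ~ U(0.6, 1.2)`) cross the 0.7 correlation threshold progressively as
  the latent factor grows — the *breadth* of supra-threshold hub links scales
  with decline;
* 120 fingerprint voxels with subject-specific loadings fixed across visits;
* a 40-voxel carrier-specific set (the group signature);
* per-site loading patterns, a motion-locked component scaled by framewise
  displacement, white noise, slow drift, and a small set of very
  high-variance "physiological" voxels standing in for CSF/head edges.

Two design constraints matter and are deliberate. First, the planted neural
sets are disjoint from each other and from the physiological set, so the
tCompCor variance ranking isolates the physiological component and never
regresses out planted structure. Second, because links are thresholded, the
hub effect is sigmoidal in the latent factor: the default
`decline_hub_strength = 1.5` centers the threshold crossing at the middle of
the carrier latent distribution, which maximizes graded separability.
Raising the strength far beyond the default *saturates* the hub (nearly all
carriers reach the complete hub graph) and separability falls again; the
monotonicity property of the generator therefore holds on the rising limb
(strengths 0–2), which is where all defaults live.

What the generator does **not** emulate: spatial autocorrelation and
hemodynamic temporal structure, registration error, scanner drift
nonlinearity, non-Gaussian score distributions, missing-not-at-random
visits, and any nonlinear decline. Passing tests on this cohort demonstrate
that the pipeline recovers the effects it assumes, with correct null
calibration — not that real data carry such effects.

## Problem sizes and runtime choices

The package's own analyses run at desk scale: 1,000 voxels (the reference
analysis used 46,667), 153 subjects, 160 frames. Unit tests use smaller
cohorts (typically 300 voxels, 64 subjects) and 100–1,000 resamples;
the acceptance checks run the full default cohort once per condition at a
fixed seed. MCD Monte-Carlo checks use 100 seeded trials; permutation
calibration uses 200 replicate null pipelines at 999 permutations.

## Known limitations

* Slopes assume linear decline; with 2 visits the slope is exact but noisy,
  and no within-subject correlation structure is modelled.
* The elastic-net hyperparameter grid is coarse (8 × 3) by design; the inner
  CV selects within it, not over a continuum.
* ComBat cannot adjust a site it has never seen; inside leave-one-site-out
  validation the held-out site passes through unadjusted unless the global
  option is chosen.
* Fingerprinting and transition analyses assume the same subject set at both
  visits; dropout handling is the caller's responsibility.
* The exact Mann-Whitney branch enumerates all assignments and is used only
  for pooled sizes ≤ 20; beyond that a tie-corrected,
  continuity-corrected normal approximation is used.
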