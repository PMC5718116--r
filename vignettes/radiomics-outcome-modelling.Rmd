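---
title: "Radiomic texture features and outcome modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic texture features and outcome modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`hccradiomics` implements a complete radiomics outcome-modelling pipeline for
hepatocellular carcinoma (HCC) radiotherapy: quantitative texture and shape
features are extracted from a planning-CT target volume, screened one at a
time against a binary local-control endpoint and a right-censored overall
survival endpoint with a mobile-threshold scan, pruned into mutually
uncorrelated groups, and fed into multivariate models — logistic regression
with backward elimination for local control, and elastic-net-regularised Cox
selection with a stepwise refit for survival — evaluated by ROC AUC,
Hosmer–Lemeshow calibration and survival calibration tables. This vignette
records the methods and, in particular, the design decisions taken where the
methodology is genuinely open.

## Image model and discretization

A case is a 3D scalar volume (`voxel_volume`) with anisotropic spacing in mm
— the defaults throughout assume planning-CT geometry, 0.8 mm in-plane and
3 mm slice thickness — and a congruent binary region of interest
(`roi_mask`), the clinical target volume (CTV). Masks are binarized at
`> 0`, so label or probabilistic masks are tolerated. IO is NIfTI
(`.nii`/`.nii.gz`) via RNifti.

Texture matrices need integer grey levels. `discretize()` maps in-mask
intensities onto `1..Ng` with equal-width bins. Two modes exist:

* **relative** (default): bins span the in-mask min–max, the maximum falling
  into bin `Ng`. Deterministic and self-contained: no assumptions about the
  underlying unit scale.
* **absolute**: caller-supplied bounds (e.g. a fixed HU window), with
  out-of-range intensities clamped into the end bins.

The default is relative binning with `Ng = 64`, a standard CT-radiomics
choice; both are configurable because the discretization actually used by
any given feature-extraction program is rarely recoverable from published
feature values. Constant-intensity ROIs are legal inputs: every voxel gets
level 1 and a degeneracy flag propagates so downstream features that are
undefined there (histogram moments, GLCM correlation) are reported as
missing with validity flags rather than dropped.

## The feature set

The extractor reports 36 named scalars across six families (the commonly
cited count for this feature set is 35, but resolving its run-length and
zone-length families into the standard short/long × low/high quartets plus
separate run and zone grey-level non-uniformities yields 36 distinct
quantities, and we keep them all):

* **Shape (2)** — sphericity $\pi^{1/3}(6V)^{2/3}/A$ and compacity
  $V/(\sqrt{\pi}\,A^{3/2})$, with $V$ the voxel-counted volume and $A$ a
  triangulated iso-surface area. A perfect sphere gives sphericity 1 and
  compacity $1/(6\pi) \approx 0.05305$.
* **Histogram (4)** — population skewness $m_3/\sigma^3$ and kurtosis
  $m_4/\sigma^4$ of the raw intensities, plus entropy
  $-\sum_i p_i \log_2 p_i$ and energy $\sum_i p_i^2$ of the binned
  histogram. Kurtosis is raw (normal $\to 3$); an excess option exists
  because both conventions circulate.
* **GLCM (6)** — homogeneity, energy, contrast, correlation, entropy,
  dissimilarity of the pooled symmetric co-occurrence probability matrix.
* **NGLDM (2)** — Amadasun–King coarseness and contrast from per-voxel
  deviations against the 26-neighbourhood mean.
* **GLRLM (11)** — the Galloway family (SRE, LRE, LGRE, HGRE, the four
  joint-weighted variants, GLNU, RLNU, RP) over maximal equal-level runs.
* **GLZLM (11)** — the same formulas with connected-component zone size
  replacing run length (SZE … ZP).

### Direction handling and anisotropy

GLCM and GLRLM use the 13 unique 3D directions at Chebyshev distance 1 and
**pool** all directions into a single matrix before computing features,
rather than averaging per-direction features. Pooling is the common 3D
practice and makes the features robust to grid-axis permutations; the
per-direction alternative would make every feature a 13-term average with
higher variance on small ROIs. Offsets are in **voxel units**: texture
deliberately ignores mm spacing (a documented limitation — on anisotropic
grids the 13 directions subtend unequal physical distances), while shape
features use spacing fully. Zone connectivity defaults to 26, configurable
to 6.

Run percentage is normalized as $N_r/(N_v \cdot D)$ with $D$ the number of
pooled directions, keeping RP in $(0,1]$ for pooled matrices; with a single
direction this reduces to the textbook $N_r/N_v$.

### Surface area

No installed mesh library provides a 3D iso-surface, so the package builds
one: marching tetrahedra (6-tetrahedron Kuhn decomposition per grid cube)
over the binary mask field. Meshing a raw binary field at the 0.5 iso-level
puts every vertex at an edge midpoint, which overstates the area of curved
surfaces by the staircase factor (around +27% for a digitized ball). The
field is therefore first anti-aliased with a weighted 27-neighbourhood
kernel (centre 4, face 2, edge 1, corner 0, normalized). The kernel is
symmetric across axis-aligned planes, so flat faces still interpolate to
their exact half-voxel positions; the test suite verifies that a digitized
radius-20 ball meshes to within 2% of the analytic sphere values and a
40×20×20 voxel box to within 5% of its closed-form area. Single-voxel and
degenerate-surface masks report shape values with `valid = FALSE`.

### NGLDM saturation

Coarseness is $1/(\varepsilon + \sum_i p_i s_i)$ with
$\varepsilon = 10^{-6}$ by default; a single occupied grey level gives
contrast 0 and coarseness saturated at $1/\varepsilon$, flagged rather than
returned as infinity.

## Univariate screening

For each covariate the **mobile threshold** scan enumerates every candidate
cut-point (midpoints of consecutive sorted distinct values), excludes splits
leaving either side below `min_frac` of the cases, evaluates the endpoint
test at each candidate, and returns the minimal-p cut. The scan is
exhaustive by construction — the test suite checks equality with an
independently coded enumeration. Ties in p break toward the smaller
threshold, making results deterministic.

* Binary endpoint: the correlation test between the dichotomized covariate
  and the 0/1 outcome (equivalent to the φ-coefficient test); a
  Mann–Whitney option is available since both tests are used in this
  screening tradition.
* Survival endpoint: the two-group log-rank test (via `survival::survdiff`)
  at each candidate split.

`min_frac` defaults to 0.10 per side. Some minimum is structurally
necessary: without one the minimal-p scan drifts to extreme splits where
the test statistic is unstable; 10% is small enough not to constrain any
plausible prognostic split at n ≈ 140.

The selected p-value is reported **raw**, uncorrected for having scanned —
that is how this screening design is conventionally reported, and the
pipeline follows it. Because selection makes raw p-values optimistic,
`threshold_permutation_p()` additionally offers a permutation-based
selection-adjusted p, clearly an extension and not used by the pipeline's
significance cut.

## Cross-correlation pruning

Covariates passing the univariate cut (p ≤ 0.05) are tested pairwise with
the Pearson correlation test on complete cases; pairs with p < 0.05 are
"cross-related". Groups are maximal sets with no internal edge, enumerated
greedily with seeds in ascending univariate-p order; each group is
internally uncorrelated by construction (asserted in tests). Every group is
modelled separately, so strongly related covariates never enter one model
together.

## Multivariate models

* **Local control**: per uncorrelated group, covariates are dichotomized at
  their screening thresholds and dealt with as factors; logistic regression
  with backward elimination drops the largest Wald p above `alpha_stay`
  (0.05) until all retained terms are significant. Complete separation is
  detected, flagged, and a small-ridge reference fit is attached. Model AUC
  uses the fitted probabilities; calibration uses Hosmer–Lemeshow with
  merged-group df adjustment when tied predictions empty a decile.
* **Survival**: significant covariates (raw values, standardized) enter an
  elastic-net-penalized Cox partial likelihood (glmnet; mixing 0.5, 100
  log-spaced lambdas, 10-fold CV with a seeded, recorded fold assignment).
  The "one standard deviation" selection rule is read as the conventional
  1-SE rule: `lambda_1se` is the largest lambda whose mean CV deviance is
  within one standard error of the minimum, i.e. the **sparser** side of
  the deviance curve. Covariates with nonzero coefficients at `lambda_1se`
  go into a backward-stepwise Cox refit (Efron ties — the standard default
  where the tie handling is otherwise unstated), reported with
  likelihood-ratio test, Wald statistics and calibration.

### AUC for a survival model

"The AUC of a Cox model" is underdetermined; the package emits two clearly
labelled variants. The default labels each case dead-vs-alive at last
follow-up and scores with the linear predictor. A horizon-restricted
variant (vital status at 12 months among cases observable to 12 months) is
also reported, since fixed-horizon discrimination is often what a reader
expects. CIs are DeLong by default, with a seeded stratified bootstrap
option (2000 resamples).

### Cox calibration

Cases are split into three risk groups on the linear predictor (ties broken
by case order so groups always form); per group and horizon (12 and 24
months by default) the mean model-predicted survival (Breslow baseline) is
tabulated against the group's Kaplan–Meier estimate. Horizons beyond the
last observed time are flagged as extrapolation.

## The synthetic cohort

No patient data ships with the package; `generate_cohort()` emulates the
study conditions so every stage is exercisable:

* n = 138 patients with survival for all and a binary response for a
  106-patient subset (missingness assigned at random, logged downstream);
* clinical covariate marginals matching the cohort demographics (54%
  portal-vein thrombosis, 70% Child–Pugh A, 72% BCLC C, 81% male, 86%
  hepatitis, age ≈ N(64, 11) clipped to 30–87, heavy-tailed AFP, doses
  54/60/66 Gy at 12/83/6%);
* 36 features drawn from a multivariate normal with a weak global
  correlation (0.15) plus strong within-family blocks (+0.45), then mapped
  affinely onto plausible reporting scales — affine maps leave thresholds,
  correlations and selection unchanged, so the scales are cosmetic;
* planted effects mirroring the intended selection pattern: survival
  driven by compacity with log-HR −1.5 per SD (hazard ratio ≈ 0.22,
  protective), response driven by histogram energy with log-odds 1.0 per
  SD;
* survival from an exponential baseline of 0.0606/month — calibrated so
  the marginal median OS is ≈ 10 months under the default censoring — with
  administrative censoring at 28 months under uniform accrual over 22
  months (median follow-up ≈ 17 months), matching the follow-up structure
  the pipeline is designed for.

The voxel-level route (`generate_lesion()`) produces digitized, optionally
lobulated ellipsoids with correlated Gaussian intensity fields: correlation
length raises GLCM homogeneity, lobulation lowers sphericity/compacity, a
skew component shifts histogram skewness. It feeds the feature-extraction
tests; the feature-level shortcut feeds the statistical tests because it is
orders of magnitude faster and its ground truth is exact.

What the generator does **not** emulate: real CT anatomy and artifacts,
segmentation/inter-observer variability, the true joint distribution of
radiomic features (which no publication provides), or any dose–response
coupling. Passing tests therefore demonstrate that the pipeline's machinery
is correct and recovers known planted structure at the study's sample
sizes — not that any particular radiomic signature generalizes to real
cohorts.

## Numerical and reproducibility choices

* Every stochastic step (cohort generation, CV folds, bootstrap,
  permutations) takes an explicit seed, and seeded helpers restore the
  caller's RNG state.
* Reruns with identical config produce byte-identical CSV/JSON outputs;
  the report bundle embeds the config echo and its MD5 hash.
* Ties: threshold ties → smaller threshold; backward elimination removes
  the single largest p each step; risk-group ties → case order.
* Degenerate inputs (constant covariates, zero-variance Cox columns,
  separation, single-level NGLDM, tied HL groups) are flagged or excluded
  with warnings, never silently dropped.
* Problem sizes in the test suite were chosen to keep the full run within
  a few minutes: brute-force feature oracles on ≥ 20 ROIs up to 6×6×3,
  threshold-search equivalence on 50 fixtures up to n = 60, 500 log-rank
  and 200 Hosmer–Lemeshow null replicates, 20-seed selection simulations
  at n = 300, and the end-to-end run at the full n = 138 design size.

## Known limitations

* Texture offsets ignore anisotropic spacing (documented above).
* NRRD input is not supported (no installed reader); NIfTI only.
* The raw selected screening p-values are optimistic by design; use the
  permutation adjustment when an honest univariate error rate matters.
* The survival-model AUC labelling mixes follow-up length into the
  dead/alive labels; prefer the 12-month variant when comparing across
  cohorts with different follow-up.
* Backward elimination and minimal-p thresholds are classical but greedy;
  neither delivers valid post-selection inference.
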