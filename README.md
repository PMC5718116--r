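# hccradiomics

Radiomic texture features and outcome modelling for hepatocellular
carcinoma (HCC) radiotherapy planning CTs.

Radiotherapy for inoperable HCC would benefit from pre-treatment markers of
local control and survival. Radiomics offers one route: quantitative
texture, histogram and shape features computed over the clinical target
volume (CTV) of the planning CT, screened against outcome and condensed
into a small prognostic signature. This package implements that analysis as
a tested, reusable pipeline:

1. **Feature extraction** — 36 features per case: shape (sphericity,
   compacity from a triangulated iso-surface), intensity histogram
   (skewness, kurtosis, entropy, energy), grey-level co-occurrence (GLCM),
   neighbourhood grey-level difference (NGLDM), run-length (GLRLM) and
   zone-length (GLZLM) families, computed on the native anisotropic grid
   with relative 64-level discretization by default.
2. **Mobile-threshold screening** — for each covariate, an exhaustive scan
   of dichotomizing cut-points keeps the one minimizing the endpoint test
   p-value: a correlation test against the binary local-control response,
   the log-rank test against overall survival. Sphericity is
   `π^(1/3)(6V)^(2/3)/A`; the threshold scan, grouping and every formula
   are documented in the methods vignette.
3. **Cross-correlation pruning** — significant covariates are split into
   maximal groups with no pair correlated at p < 0.05, so related features
   never share a model.
4. **Modelling** — per group, logistic regression with backward
   elimination on the thresholded factors (local control); elastic-net
   penalized Cox with the 1-SE rule followed by stepwise refit (survival,
   Efron ties). Evaluation by ROC AUC with DeLong CIs, Hosmer–Lemeshow
   calibration, and predicted-vs-Kaplan–Meier calibration tables at 12 and
   24 months.
5. **Synthetic cohort** — since no patient data is distributable, a seeded
   generator emulates the study design (n = 138, survival for all, binary
   response for a 106-patient subset, realistic clinical marginals, median
   OS ≈ 10 months) with planted effects: compacity drives survival
   (log-HR −1.5 per SD), histogram energy drives response. Every pipeline
   stage is tested end to end against this generator and against
   brute-force oracles.

## Worked example

```r
library(hccradiomics)

cohort <- generate_cohort(n_total = 138, n_response_subset = 106, seed = 1)
res <- run_pipeline(cohort, pipeline_config(seed = 1), out_dir = "report")
print(res)
```

```
<pipeline_result>
  response screening: 48 covariates, 16 significant
  response model 1: age+energy_H+glcm_energy+ngldm_contrast+RLNU (AUC 0.8479)
  response model 2: energy_H+ngldm_coarseness+LZHGE (AUC 0.7836)
  ...
  survival screening: 48 covariates, 30 significant
  survival model: compacity (AUC 0.8679)
  median OS: 9.96 months
```

The survival branch screens all 48 covariates (12 clinical + 36 radiomic),
finds 30 significant at the mobile-threshold log-rank cut, and after
elastic-net selection and stepwise refit retains the planted signature —
compacity alone:

```r
print(res$model_survival)
```

```
<model_fit> endpoint survival: 1 covariate(s) retained
          estimate      se       z p
compacity  -134.92 15.5071 -8.7005 0
LR test: stat 94.429, p 2.54e-22; AUC 0.8679 (0.8069-0.9289)
```

The coefficient is on the raw compacity scale (SD ≈ 0.01 here); per SD it
corresponds to a hazard ratio of ≈ 0.22 — large compact (regular-shaped)
lesions carry lower hazard in this synthetic design. The `report/`
directory holds the full bundle: univariate tables, correlation matrices,
uncorrelated groups, model summaries (JSON), calibration tables and the
omitted-cases log.

A thin command-line wrapper over the same functions is installed at
`inst/cli/hccradiomics.R` (subcommands `extract`, `screen`, `simulate`,
`run`).

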