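# ubcsig

Gene-signature subtyping and overall-survival modelling for urothelial
bladder cancer (UBC).

Bulk RNA-seq studies split UBC into **basal** and **luminal** molecular
subtypes with distinct prognosis. `ubcsig` packages the computational
workflow behind that kind of study for re-use: starting from a raw
gene-by-sample count matrix and a clinical table, it normalizes
expression, merges cohorts across batches, classifies tumors from a
STAT3/FOSL1-style gene signature, selects the signature genes that are
*stable* under resampling, and asks whether the signature predicts
overall survival. A pathology-side module scores the four-marker
immunohistochemistry (IHC) panel (CK5/6, CK14, CK20, UPK2) and calls
basal / luminal / non-type per case. It is aimed at computational
biologists and biostatisticians who want each of these steps as a
tested, scriptable unit rather than a one-off analysis.

Because the cohorts such studies use (TCGA bladder, GEO series) are not
redistributable, the package ships a synthetic-cohort generator with the
same statistical structure — negative-binomial counts with a
basal-vs-luminal differential signature, batch effects, and Weibull
survival with a linear log-hazard in the signature — so every stage is
testable offline.

## What is implemented

| Stage | Method |
|---|---|
| Normalization | duplicate-sample averaging, TMM library-size factors, log2-RPKM, log-CPM |
| Batch merging | parametric empirical-Bayes location/scale adjustment (the ComBat model): per-batch γ\*, δ\*² shrunk toward normal / inverse-gamma priors |
| Subtype classifier | elastic-net logistic regression, −(1/n)ℓ(β) + λ(α‖β‖₁ + (1−α)/2‖β‖₂²), with *joint* (α, λ) 10-fold CV, balanced 70–30 split, Clopper–Pearson accuracy CI |
| Stable gene selection | stability path over class-stratified half-samples, first *q* genes to enter the lasso path with q²/((2π−1)p) ≤ PCER·p; and bootstrap-Lasso ("Boot Lasso", B resamples, ≥50 % retention, ridge refit) |
| Survival | univariate Cox screen; ridge/lasso-penalized Cox (Breslow baseline); IPCW Brier score BS(t) and its integral over [0, 3] years, 10-fold cross-validated; nearest-neighbor conditional Kaplan–Meier; maximally selected log-rank cut points with improved-Bonferroni adjusted p |
| Differential expression | voom precision weights + moderated t with empirical-Bayes variance shrinkage s²ₚₒₛₜ = (d₀s₀² + d s²)/(d₀ + d); ΔΔCT qPCR quantification with Student t + BH FDR |
| IHC subtyping | four-tier percent-positive scoring (UPK2-specific cut-offs), basal/luminal/non-type decision rules, high/low dichotomization, 2×2 contingency tests |

The central container is `UBCCohort`, a `SummarizedExperiment` with a
`counts` assay, gene lengths in `rowData()` and clinical annotation in
`colData()`; results are S4 objects with accessors
(`normFactors()`, `stableSet()`, `ibs()`, `cutQuantile()`, ...).

## Worked example

```r
library(ubcsig)

cohort <- generateCohort(syntheticConfig(
  nSamples = 200, nGenes = 300, nSignatureGenes = 13, log2Effect = 2,
  basalFraction = 0.4, coxBetas = c(g0001 = 1, g0002 = -0.8),
  targetCensoring = 0.4, seed = 42))

expr <- log2RPKM(cohort, tmmFactors(cohort))
ann  <- as.data.frame(SummarizedExperiment::colData(cohort))
sig  <- S4Vectors::metadata(cohort)$truth$signature_genes

X <- signatureMatrix(expr, sig)
y <- setNames(as.character(ann$subtype), rownames(X))
split   <- splitTrainTest(y, 0.7, seed = 1)
model   <- fitElasticNetLogistic(X[split$trainIds, ], y[split$trainIds],
                                 nFolds = 10, seed = 2)
metrics <- evaluateClassifier(model, X[split$testIds, ], y[split$testIds])
metrics
#> ClassifierMetrics: accuracy 1.000 (95% CI 0.940-1.000, clopper-pearson)
#>   sensitivity 1.000, specificity 1.000, n = 60
```

The classifier separates the two subtypes perfectly on this test set of
60; the exact binomial interval says the accuracy is at least 0.94 with
95 % confidence. Selecting stable signature genes from the *full*
300-gene panel:

```r
Xall <- t(exprValues(expr))
stab <- stabilityPathSelect(Xall[split$trainIds, ], y[split$trainIds],
                            seed = 3)
stab
#> StabilitySelectionResult: 12 stable genes (pi = 0.8 , PCER = 0.1 , q = 73 , 100 subsamples)
#>   g0001, g0002, g0003, g0004, g0005, g0006, g0007, g0008, g0010, g0011 ...
```

Twelve of the thirteen planted signature genes are recovered with no
false positives. Survival prediction, comparing the ridge-penalized
signature model against the no-covariate Kaplan–Meier baseline by
cross-validated integrated Brier score:

```r
curves <- cvPredictionError(X, ann$os_time, ann$os_event,
                            models = c("null", "full_signature"),
                            nFolds = 10, seed = 4)
curves$full_signature
#> PredictionErrorCurve [full_signature]: IBS 0.0959 over [0, 3] years (94 grid times)
curves$null
#> PredictionErrorCurve [null]: IBS 0.1088 over [0, 3] years (94 grid times)

ridge <- fitRidgeCox(X, ann$os_time, ann$os_event, seed = 5)
maxstatCutpoint(as.numeric(X %*% modelCoef(ridge)),
                ann$os_time, ann$os_event)
#> CutpointResult: cut 3.109 at quantile 0.78, M = 7.180, adjusted p = 8.01e-11
```

A lower IBS for the signature model (0.096 vs 0.109) means the
signature improves 3-year survival prediction over the null model, and
the maximally selected log-rank statistic locates a highly significant
prognostic cut in the signature distribution.

`runPipeline(demoRunConfig("out/"))` chains all stages (including batch
adjustment and Boot Lasso) and writes every intermediate artifact plus a
`report.json` under `out/`.

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch on the
bundled synthetic demo configuration — cohort generation, normalization,
batch adjustment, classification with stability selection, and the
survival analyses — and writes its target map as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Repository layout

- `R/` — implementation (S4 classes in `AllClasses.R`, one file per
  analysis stage)
- `tests/testthat/` — unit, property and acceptance tests, with
  independently coded brute-force oracles in `helper-oracles.R`
- `vignettes/ubcsig-methods.Rmd` — the methods vignette: models,
  assumptions, numerical choices and limitations
- `scripts/acceptance.R` — end-to-end acceptance run
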