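---
title: "Methods: signature subtyping and survival modelling in ubcsig"
author: "ubcsig maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature subtyping and survival modelling in ubcsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models the package implements, the tunable
parameters that matter, the numerical conventions, and the design
choices made where the methods literature leaves the design open. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The synthetic cohort: a stated world

Every stochastic claim in the test suite is evaluated against cohorts
from `generateCohort()`, so the generator's assumptions bound what a
green test establishes.

**Counts.** Gene *g*, sample *s* receives a negative-binomial draw with
dispersion φ (`nbDispersion`, default 0.2, a typical bulk RNA-seq
value) and

log2 μ_gs = baseline_g + Δ·1{g ∈ signature, s basal} + batch_b(g, s) + log2(libfactor_s),

with baseline counts lognormal(meanlog 4, sdlog 1.5) to span the
RNA-seq dynamic range, Δ (`log2Effect`, default 2) the per-gene subtype
separation, and library factors uniform on `libsizeRange` (default
0.5–1.5). Defaults describe a TCGA-bladder-like cohort: 388
de-duplicated samples, a 13-gene signature, 40 % basal.

**Batches.** Batch 1 is the reference. For batches ≥ 2, a fraction
`batchAffectedFraction` (default 0.5) of genes receives the additive
log2 shift `batchShift` plus per-observation Gaussian log2 noise with
variance log2(`batchScale`) — a location shift and a variance inflation,
i.e. the location/scale structure the empirical-Bayes adjustment of
Section 3 assumes. The per-observation (rather than per-gene-constant)
noise is what actually inflates within-batch variance.

**Survival.** With η_s = Σ_g β_g z_gs on per-gene standardized log2
expression of the generated cohort itself (the standardization keeps the
β scale-free; it is computed on the realized data, not the latent
means), event times are Weibull:
T = (−log U / (λ0 e^η))^(1/k), shape k (`weibullShape`, 1.2) and
baseline rate λ0 (`baselineRate`, 0.1/year). Censoring is exponential
with its rate calibrated by deterministic bisection on the drawn event
times to hit `targetCensoring` (default 0.5 — the source cohorts do not
report their censoring fraction, so this is a placeholder, not an
estimate). The whole cohort is a pure function of the seed.

**What the generator does not emulate:** read-level structure, gene–gene
correlation beyond what the subtype/batch factors induce, isoforms, GC
or length bias, non-proportional hazards, informative censoring. Green
tests therefore establish correctness of the *procedures* and their
behavior under the stated model, not robustness to those features of
real data.

The IHC generator draws percent-positive values per marker from
subtype-conditional Beta distributions with precision ν = 20; the means
(e.g. basal CK5/6 0.70 vs luminal 0.05) were fixed once, before any
end-to-end testing, to reflect how strongly these markers separate
subtypes in pathology practice.

## 2. Normalization

TMM factors use the published estimator with its canonical defaults —
30 % two-sided trim on M-values, 5 % on A-values, inverse delta-method
variance weights, reference sample = the one whose 75th-percentile count
fraction is closest to the mean — delegated to edgeR's implementation
behind the package's own surface, and cross-checked in the tests against
an independently written brute-force transcription to 1e-10.

log2-RPKM is `log2((count + c) / (effLib/1e6 · length/1e3))` with
effective library size = column sum × TMM factor. The pseudocount c and
whether effective libraries enter RPKM are not standardized in the
field; both are explicit arguments, with c = 0.5 the default for both
RPKM and log-CPM (uniform across samples, so the downstream penalized
models are insensitive to the constant). Duplicate-sample averaging
rounds half-to-even to keep integer count semantics; technical replicate
structure is supplied as a sample→case map, FFPE exclusion is a pure
metadata filter.

## 3. Batch adjustment

`combatAdjust()` is a from-scratch implementation of the parametric
empirical-Bayes location/scale model (the package environment does not
ship an implementation): standardize each gene by its grand mean,
retained covariate effects and pooled variance; estimate per-batch
per-gene location γ̂ and scale δ̂²; fit a normal prior for γ and an
inverse-gamma prior for δ² across genes by method of moments; iterate
the coupled posterior-mean updates to a relative tolerance of 1e-6
(maximum 5000 iterations, error on non-convergence); back-transform
with the shrunk γ\*, δ\*².

Two conventions worth stating:

* **Subtype as covariate.** For external validation the class label is
  unknown at prediction time, so the default adjusts *without* it;
  `covariates=` accepts a design matrix when adjusting a labelled
  cohort. Whether the original analyses conditioned on subtype is not
  documented; both modes exist and the default is a choice, not a claim.
* **What adjustment cannot do.** Exact grand-mean preservation per gene
  is *not* an EB property (γ\* is shrunk toward the batch prior mean, so
  Σ_b n_b γ\*_bg ≠ 0 in general); the tests check approximate
  preservation. Likewise, the post-adjustment between-batch variance
  ratio cannot concentrate arbitrarily: two independent n=100 variance
  estimates have an F(99, 99) ratio even under perfect adjustment, so
  only ~73 % of genes would fall in [0.8, 1.25] for an oracle; the EB
  adjustment reaches ~93 % because both batches are standardized with
  the same estimates. The recovery test asserts ≥ 90 %.

## 4. Subtype classification

The classifier is elastic-net logistic regression (glmnet) on the
signature genes, standardized internally with back-transformed
coefficients, basal encoded as 1, probability threshold fixed at 0.5.
Tuning is *joint* over (α, λ): α grid {0, 0.25, 0.5, 0.75, 1}, a
100-value λ path spanning four decades per α, shared stratified 10-fold
assignments, mean CV binomial deviance as the criterion. λ ties break
toward the larger (more parsimonious) value; the grids and tie-break are
package choices — the source methodology states joint tuning but not the
grids. Balanced 70–30 splitting takes `round(0.7 · n_c)` training
samples per class.

Accuracy intervals are exact Clopper–Pearson by default (this
reproduces the shape of printed intervals such as 110/117 → 0.88–0.98);
a bootstrap percentile CI is available for the workflows that reported
bootstrap intervals.

**Stability path.** Each of `nSubsamples` (default 100) class-stratified
half-samples contributes its first *q* genes to enter the lasso path,
with q the largest integer satisfying the per-comparison error bound
q²/((2π−1)p) ≤ PCER·p (π = 0.8, PCER = 0.1). Genes at or above
frequency π form the stable set. The first-*q*-to-enter (path-order)
rule rather than a fixed λ makes *q* interpretable and matches the
stability-path formulation; whether the original analyses used
path-order or fixed-λ selection is not stated. Ties within one path
step are broken by coefficient magnitude at entry.

## 5. Survival modelling

Conventions used throughout: times are years; ties are handled by
Breslow everywhere (Efron available where the backend supports it);
the Breslow cumulative baseline hazard is estimated on training data so
S(t|x) = exp(−H₀(t)e^η) is available from every fitted model; the null
model is the training Kaplan–Meier itself (its curve is reproduced
exactly through H₀ = −log S_KM).

**Penalty tuning.** Ridge (and lasso) Cox λ comes from 10-fold CV of the
partial-likelihood deviance at `lambda.min`. Inside **Boot Lasso**,
each of B bootstrap resamples (paper value B = 200; the acceptance
simulations scale to B = 50) runs a lasso Cox whose λ is chosen by CV
*within that bootstrap* at the parsimonious `lambda.1se` rule, and genes
with nonzero coefficients in ≥ 50 % of resamples are retained for a
ridge refit. The `lambda.1se` choice is deliberate: bootstrap resamples
of one dataset share its chance correlations, and at `lambda.min` those
spurious genes recur across resamples, so a global-null cohort would
not yield an empty retained set — the behavior bootstrap-Lasso selection
exists to provide. An empty retained set falls back to the null
predictor, flagged.

**Prediction error.** BS(t) is the IPCW form with Ĝ the Kaplan–Meier of
censoring on the evaluation data, left limits Ĝ(T⁻) at event times,
samples censored before t contributing zero, and an explicit error when
a required weight falls below 1e-8 (no silent truncation). The IBS is
the trapezoidal time-average over [0, t_max = 3] years on the grid of
observed times in (0, t_max], with 0 and t_max included as quadrature
endpoints (so a constant curve integrates to itself). Cross-validated
curves pool the out-of-fold survival predictions and run one Brier/IBS
computation on the pooled matrix; per-fold averaging is the obvious
alternative and either could be behind published numbers — pooling is
implemented.

**Conditional Kaplan–Meier.** Rectangular-kernel nearest-neighbor
estimates at the smallest, median and largest signature value:
neighborhood = the ⌈span·n⌉ samples closest in signature value (ties by
sample order), span defaulting to 0.25 (the estimator's bandwidth is
not standardized; span = 1 recovers the global KM exactly, which the
tests exploit).

**Cut points.** The maximally selected log-rank statistic scans every
observed cut with quantile in [ε₁, ε₂] = [0.1, 0.9], computes the
standardized two-group log-rank statistic (hypergeometric variance) and
takes M = max |Z|. The adjusted p is the Brownian-bridge
improved-Bonferroni approximation
p ≈ 4φ(b)/b + φ(b)(b − 1/b)·log(ε₂(1−ε₁)/(ε₁(1−ε₂))),
capped at 1, floored at the pointwise two-sided normal p, returning 1
outright for b ≤ 1 (where the approximation is vacuous). A degenerate
ε range with a single candidate cut returns the pointwise p exactly.
The approximation is conservative for discrete cut sets, which the null
calibration test reflects.

## 6. Differential expression and qPCR

voom precision weights (log-CPM with prior 0.5, lowess span 0.5, weight
= predicted sd⁻⁴) come from limma. The moderated t-statistic is
implemented in the package: per-gene weighted least squares, empirical-
Bayes variance shrinkage s²ₚₒₛₜ = (d₀s₀² + d_g s²_g)/(d₀ + d_g) with
(d₀, s₀²) from closed-form moment matching on log variances
(digamma/trigamma inversion by Newton), t referred to d₀ + d_g degrees
of freedom, BH FDR across genes. The hand implementation exists because
the limit behaviors (forced d₀ = 0 → ordinary t; d₀ = ∞ → z with s₀²)
are part of the contract; limma's eBayes serves as the independent
cross-check in the tests (agreement to 1e-8 on heteroscedastic
fixtures).

ΔΔCT quantification averages duplicate wells per sample, forms
ΔCT = CT_target − CT_reference, ΔΔCT against the calibrator condition's
mean, FC = 2^−ΔΔCT, and compares replicate ΔCT values by a pooled-
variance Student t (Welch behind a flag), with BH applied across genes
within each condition (whether the original correction pooled
conditions is not stated).

## 7. IHC scoring and subtype calls

Tier boundaries are half-open with the printed "≥" anchors honored:
standard markers [0,5)→0, [5,25)→1, [25,50)→2, [50,100]→3; UPK2 is 0
only for a fully negative stain, then (0,10)→1, [10,25)→2, [25,100]→3.
The published ranges overlap at their endpoints, so a convention was
required; this one keeps each anchor value in the higher tier.

The basal/luminal decision evaluates both sides independently:

* basal (i): CK5/6 = 3 or CK14 = 3 — *not* conditioned on luminal
  markers;
* basal (ii): CK5/6 = CK14 = 2 with CK20, UPK2 ≤ 1;
* luminal (i): CK20 = 3 unconditionally, or UPK2 ∈ {2, 3} with
  CK5/6, CK14 ≤ 1;
* luminal (ii): CK20, UPK2 ∈ {1, 2} with CK5/6, CK14 ≤ 1.

Both sides true ⇒ non-type with a `conflict` flag; neither ⇒ non-type.
The published wording does not pin down which clauses carry the
"absent/focal basal markers" condition; the attachment above is the
unique convention consistent with both boundary cases the package
treats as fixed points ((2,1,2,2) → non-type; CK5/6 = 3 with CK20 = 3 →
conflict). The flag makes conflicted calls auditable downstream.
High/low dichotomization is tier ≥ 2. Contingency tests default to
Pearson χ² without continuity correction, with Yates and Fisher
variants recorded in the output — printed p-values in the motivating
literature are consistent with corrected/exact variants, so the variant
is never implicit.

## 8. Pipeline and reproducibility

`runPipeline()` validates its configuration upfront (every enabled
stage must have resolvable inputs), expands the single global seed
deterministically into per-stage seeds, writes every intermediate
artifact as TSV/JSON, never mutates an input, and embeds an MD5 hash of
the analysis parameters (output paths excluded) in the report. Reruns
with the same configuration are byte-identical on the data artifacts.

## 9. Known limitations

* Only overall survival is modelled: no competing risks, time-varying
  covariates or disease-specific endpoints.
* The classifier is strictly binary; non-type cases are excluded from
  training rather than modelled as a third class.
* Gene matching across datasets is exact-string only.
* The maxstat adjusted p uses one specific (conservative) approximation;
  permutation p-values are not implemented.
* The EB batch adjustment is the parametric variant only — no
  non-parametric priors, reference-batch mode, or missing-value
  handling beyond complete rows.
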