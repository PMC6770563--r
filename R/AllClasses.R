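#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats approx coef fisher.test chisq.test glm median na.omit
#'   p.adjust pnorm pt quantile rbeta rbinom rexp rlnorm rnbinom rnorm runif
#'   sd setNames t.test var binom.test predict model.matrix density
#' @importFrom utils head read.delim write.table
NULL

#' Cohort container for bladder-cancer signature analyses
#'
#' `UBCCohort` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with the conventions every stage of the pipeline relies on: a `"counts"`
#' assay of non-negative integers, a `length_bp` column in `rowData()` giving
#' gene lengths in base pairs, and per-sample clinical annotation in
#' `colData()` (`subtype`, `batch`, `os_time`, `os_event` where available).
#' Ground-truth simulation parameters live in `metadata(x)$truth` for
#' synthetic cohorts.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [generateCohort()], [readCountMatrix()]
#' @export
setClass("UBCCohort", contains = "SummarizedExperiment")

setValidity("UBCCohort", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(cnt - round(cnt)) > 1e-8)) msg <- c(msg, "counts must be integers")
  }
  if (!"length_bp" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain 'length_bp'")
  else if (any(SummarizedExperiment::rowData(object)$length_bp <= 0))
    msg <- c(msg, "gene lengths must be strictly positive")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' TMM normalization factors
#'
#' Per-sample trimmed-mean-of-M-values library-size factors, rescaled to
#' geometric mean one, together with the reference sample and the trim
#' fractions used.
#'
#' @slot factors Named numeric vector of positive factors (geometric mean 1).
#' @slot referenceSample Sample id used as the M/A reference.
#' @slot trimM,trimA Trim proportions applied to M and A values.
#' @export
setClass("TMMResult",
  representation(factors = "numeric", referenceSample = "character",
                 trimM = "numeric", trimA = "numeric"))

setValidity("TMMResult", function(object) {
  f <- object@factors
  if (any(f <= 0)) return("factors must be positive")
  if (abs(sum(log(f))) > 1e-9 * max(1, length(f)))
    return("factors must have geometric mean 1")
  TRUE
})

#' Expression matrix with transform metadata
#'
#' A genes-by-samples real matrix remembering which transform produced it
#' (`log2_rpkm` or `log_cpm`), the pseudocount, and the effective library
#' sizes used.
#'
#' @slot values Numeric matrix, genes x samples.
#' @slot transform `"log2_rpkm"` or `"log_cpm"`.
#' @slot pseudocount Non-negative prior count added before the log.
#' @slot effectiveLibsizes Per-sample effective library sizes.
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", transform = "character",
                 pseudocount = "numeric", effectiveLibsizes = "numeric"))

setValidity("ExpressionMatrix", function(object) {
  if (!all(is.finite(object@values))) return("values must be finite")
  if (!object@transform %in% c("log2_rpkm", "log_cpm", "adjusted"))
    return("unknown transform")
  if (object@pseudocount < 0) return("pseudocount must be >= 0")
  TRUE
})

#' Empirical-Bayes batch-adjustment parameters
#'
#' All quantities estimated by [combatAdjust()]: per-batch per-gene location
#' (`gammaHat`, shrunk `gammaStar`) and scale (`delta2Hat`, shrunk
#' `delta2Star`) estimates, the normal / inverse-gamma prior hyperparameters,
#' the grand mean and pooled variance per gene, and any retained covariate
#' coefficients.
#'
#' @export
setClass("ComBatParams",
  representation(gammaHat = "matrix", gammaStar = "matrix",
                 delta2Hat = "matrix", delta2Star = "matrix",
                 gammaBar = "numeric", tau2 = "numeric",
                 aPrior = "numeric", bPrior = "numeric",
                 alphaHat = "numeric", sigma2Hat = "numeric",
                 covariateCoef = "matrix", batches = "character",
                 iterations = "integer"))

#' Elastic-net logistic subtype classifier
#'
#' @slot intercept Intercept on the logit scale.
#' @slot coefficients Named per-gene coefficients (training gene order).
#' @slot alpha Elastic-net mixing parameter selected by CV.
#' @slot lambda Penalty strength selected by CV.
#' @slot cvTable data.frame of mean CV binomial deviance over (alpha, lambda).
#' @slot positiveClass Label encoded as 1 (default `"basal"`).
#' @export
setClass("ElasticNetModel",
  representation(intercept = "numeric", coefficients = "numeric",
                 alpha = "numeric", lambda = "numeric",
                 cvTable = "data.frame", positiveClass = "character"))

#' Classifier performance metrics
#'
#' @slot accuracy,sensitivity,specificity Proportions on the test set.
#' @slot accuracyCI Two-sided 95 percent interval for the accuracy.
#' @slot confusion 2x2 integer table, predicted x truth.
#' @slot ciMethod `"clopper-pearson"` or `"bootstrap"`.
#' @export
setClass("ClassifierMetrics",
  representation(accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", accuracyCI = "numeric",
                 confusion = "matrix", ciMethod = "character"))

setValidity("ClassifierMetrics", function(object) {
  n <- sum(object@confusion)
  acc <- sum(diag(object@confusion)) / n
  if (abs(acc - object@accuracy) > 1e-12)
    return("accuracy does not recompute from the confusion table")
  ci <- object@accuracyCI
  if (!(ci[1] <= object@accuracy + 1e-12 && object@accuracy <= ci[2] + 1e-12))
    return("accuracy outside its own confidence interval")
  TRUE
})

#' Stability-path selection result
#'
#' Per-gene selection frequencies over class-stratified half-sample
#' subsamples and the stable set at threshold pi, with the per-comparison
#' error-rate bound that fixed the per-subsample selection count q.
#'
#' @slot selectionFrequency Named frequencies in \[0, 1\].
#' @slot stableSet Gene ids with frequency >= `piThreshold`.
#' @slot piThreshold,pcer Stability threshold and per-comparison error rate.
#' @slot q Genes retained per subsample (first q to enter the lasso path).
#' @slot nSubsamples Number of half-sample draws.
#' @export
setClass("StabilitySelectionResult",
  representation(selectionFrequency = "numeric", stableSet = "character",
                 piThreshold = "numeric", pcer = "numeric", q = "integer",
                 nSubsamples = "integer"))

setValidity("StabilitySelectionResult", function(object) {
  ss <- names(object@selectionFrequency)[
    object@selectionFrequency >= object@piThreshold]
  if (!setequal(ss, object@stableSet))
    return("stableSet must equal genes at or above the pi threshold")
  TRUE
})

#' Penalized Cox survival model with Breslow baseline
#'
#' @slot coefficients Named per-gene log-hazard coefficients.
#' @slot penalty `"ridge"`, `"lasso"` or `"none"`.
#' @slot lambda Penalty strength (0 for unpenalized).
#' @slot baselineTime,baselineHazard Breslow cumulative-hazard step function
#'   estimated on the training data (hazard for the linear predictor at 0).
#' @slot nullModel TRUE for the covariate-free Kaplan-Meier fallback.
#' @export
setClass("CoxSignatureModel",
  representation(coefficients = "numeric", penalty = "character",
                 lambda = "numeric", baselineTime = "numeric",
                 baselineHazard = "numeric", nullModel = "logical"))

setValidity("CoxSignatureModel", function(object) {
  if (is.unsorted(object@baselineHazard))
    return("baseline cumulative hazard must be non-decreasing")
  if (!all(is.finite(object@coefficients)))
    return("coefficients must be finite")
  TRUE
})

#' Bootstrap-Lasso ("Boot Lasso") selection result
#'
#' @slot B Number of bootstrap resamples.
#' @slot selectionCount Named per-gene count of bootstraps with nonzero lasso
#'   coefficient.
#' @slot retainedSet Genes selected in at least `retainFraction` of resamples.
#' @slot retainFraction Retention threshold (paper default 0.5).
#' @slot finalModel Ridge [CoxSignatureModel-class] on the retained genes
#'   (null predictor when the retained set is empty).
#' @slot emptySet Flag: no gene met the retention threshold.
#' @export
setClass("BootLassoResult",
  representation(B = "integer", selectionCount = "numeric",
                 retainedSet = "character", retainFraction = "numeric",
                 finalModel = "CoxSignatureModel", emptySet = "logical"))

setValidity("BootLassoResult", function(object) {
  keep <- names(object@selectionCount)[
    object@selectionCount / object@B >= object@retainFraction]
  if (!setequal(keep, object@retainedSet))
    return("retainedSet must equal genes at or above the retention threshold")
  TRUE
})

#' Time-dependent prediction-error curve
#'
#' IPCW Brier scores on a time grid and their integrated (trapezoidal
#' time-averaged) value over \[0, tMax\].
#'
#' @slot times Evaluation grid (years).
#' @slot brier BS(t) at each grid time.
#' @slot ibs Integrated Brier score over \[0, tMax\].
#' @slot tMax Upper integration limit in years (default 3).
#' @slot modelLabel `"null"`, `"full_signature"` or `"boot_lasso"`.
#' @export
setClass("PredictionErrorCurve",
  representation(times = "numeric", brier = "numeric", ibs = "numeric",
                 tMax = "numeric", modelLabel = "character"))

setValidity("PredictionErrorCurve", function(object) {
  if (any(object@brier < -1e-12 | object@brier > 1 + 1e-12))
    return("Brier scores must lie in [0, 1]")
  TRUE
})

#' Maximally selected log-rank cut point
#'
#' @slot cutValue Value of the predictor at the selected cut.
#' @slot cutQuantile Empirical quantile of the cut in (0, 1).
#' @slot maxStatistic Maximum absolute standardized log-rank statistic M.
#' @slot adjustedP Multiplicity-adjusted p-value (improved-Bonferroni
#'   Brownian-bridge approximation), capped at 1.
#' @slot epsilon Quantile search bounds (low, high).
#' @export
setClass("CutpointResult",
  representation(cutValue = "numeric", cutQuantile = "numeric",
                 maxStatistic = "numeric", adjustedP = "numeric",
                 epsilon = "numeric"))

setValidity("CutpointResult", function(object) {
  eps <- object@epsilon
  if (object@cutQuantile < eps[1] - 1e-9 || object@cutQuantile > eps[2] + 1e-9)
    return("cut quantile outside the epsilon search range")
  TRUE
})
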