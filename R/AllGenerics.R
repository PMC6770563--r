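# Accessors and show methods. Slot access from user code is discouraged;
# these are the supported surface.

#' @rdname TMMResult-class
#' @param object,x An object of the documented class.
#' @export
setGeneric("normFactors", function(object) standardGeneric("normFactors"))

#' @rdname TMMResult-class
#' @export
setMethod("normFactors", "TMMResult", function(object) object@factors)

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprTransform", function(object) standardGeneric("exprTransform"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprTransform", "ExpressionMatrix", function(object) object@transform)

#' @rdname ElasticNetModel-class
#' @export
setGeneric("modelCoef", function(object) standardGeneric("modelCoef"))

#' @rdname ElasticNetModel-class
#' @export
setMethod("modelCoef", "ElasticNetModel", function(object)
  c("(Intercept)" = object@intercept, object@coefficients))

#' @rdname CoxSignatureModel-class
#' @export
setMethod("modelCoef", "CoxSignatureModel", function(object) object@coefficients)

#' @rdname StabilitySelectionResult-class
#' @export
setGeneric("stableSet", function(object) standardGeneric("stableSet"))

#' @rdname StabilitySelectionResult-class
#' @export
setMethod("stableSet", "StabilitySelectionResult", function(object)
  object@stableSet)

#' @rdname StabilitySelectionResult-class
#' @export
setGeneric("selectionFrequency",
           function(object) standardGeneric("selectionFrequency"))

#' @rdname StabilitySelectionResult-class
#' @export
setMethod("selectionFrequency", "StabilitySelectionResult", function(object)
  object@selectionFrequency)

#' @rdname BootLassoResult-class
#' @export
setGeneric("retainedSet", function(object) standardGeneric("retainedSet"))

#' @rdname BootLassoResult-class
#' @export
setMethod("retainedSet", "BootLassoResult", function(object) object@retainedSet)

#' @rdname PredictionErrorCurve-class
#' @export
setGeneric("ibs", function(object) standardGeneric("ibs"))

#' @rdname PredictionErrorCurve-class
#' @export
setMethod("ibs", "PredictionErrorCurve", function(object) object@ibs)

#' @rdname ClassifierMetrics-class
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' @rdname ClassifierMetrics-class
#' @export
setMethod("accuracy", "ClassifierMetrics", function(object) object@accuracy)

#' @rdname CutpointResult-class
#' @export
setGeneric("cutQuantile", function(object) standardGeneric("cutQuantile"))

#' @rdname CutpointResult-class
#' @export
setMethod("cutQuantile", "CutpointResult", function(object) object@cutQuantile)

setMethod("show", "TMMResult", function(object) {
  cat("TMMResult:", length(object@factors), "samples, reference",
      object@referenceSample, "\n")
  cat("  trim: M", object@trimM, "/ A", object@trimA, "\n")
  cat("  factor range:",
      paste(signif(range(object@factors), 4), collapse = " - "), "\n")
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object@values), "genes x",
      ncol(object@values), "samples (", object@transform,
      ", pseudocount", object@pseudocount, ")\n")
})

setMethod("show", "ElasticNetModel", function(object) {
  nz <- sum(object@coefficients != 0)
  cat("ElasticNetModel: alpha =", object@alpha,
      ", lambda =", signif(object@lambda, 4),
      ",", nz, "of", length(object@coefficients), "nonzero genes\n")
})

setMethod("show", "ClassifierMetrics", function(object) {
  cat(sprintf(
    "ClassifierMetrics: accuracy %.3f (95%% CI %.3f-%.3f, %s)\n",
    object@accuracy, object@accuracyCI[1], object@accuracyCI[2],
    object@ciMethod))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, n = %d\n",
              object@sensitivity, object@specificity, sum(object@confusion)))
})

setMethod("show", "StabilitySelectionResult", function(object) {
  cat("StabilitySelectionResult:", length(object@stableSet),
      "stable genes (pi =", object@piThreshold, ", PCER =", object@pcer,
      ", q =", object@q, ",", object@nSubsamples, "subsamples)\n")
  if (length(object@stableSet))
    cat(" ", paste(head(object@stableSet, 10), collapse = ", "),
        if (length(object@stableSet) > 10) "..." else "", "\n")
})

setMethod("show", "CoxSignatureModel", function(object) {
  if (object@nullModel) {
    cat("CoxSignatureModel: null model (Kaplan-Meier, no covariates)\n")
  } else {
    cat("CoxSignatureModel:", object@penalty, "penalty, lambda =",
        signif(object@lambda, 4), ",", sum(object@coefficients != 0),
        "nonzero of", length(object@coefficients), "genes\n")
  }
})

setMethod("show", "BootLassoResult", function(object) {
  cat("BootLassoResult: B =", object@B, ", retain >=",
      object@retainFraction, "->", length(object@retainedSet),
      "genes retained", if (object@emptySet) "(empty set)" else "", "\n")
})

setMethod("show", "PredictionErrorCurve", function(object) {
  cat(sprintf("PredictionErrorCurve [%s]: IBS %.4f over [0, %g] years (%d grid times)\n",
              object@modelLabel, object@ibs, object@tMax,
              length(object@times)))
})

setMethod("show", "CutpointResult", function(object) {
  cat(sprintf(
    "CutpointResult: cut %.4g at quantile %.2f, M = %.3f, adjusted p = %.4g\n",
    object@cutValue, object@cutQuantile, object@maxStatistic,
    object@adjustedP))
})

setMethod("show", "ComBatParams", function(object) {
  cat("ComBatParams:", length(object@batches), "batches,",
      length(object@alphaHat), "genes,", object@iterations,
      "EB fixed-point iterations\n")
})

setMethod("show", "UBCCohort", function(object) {
  callNextMethod()
  tr <- S4Vectors::metadata(object)$truth
  if (!is.null(tr))
    cat("synthetic truth:", length(tr$signature_genes),
        "signature genes,", length(tr$cox_betas), "prognostic genes\n")
})
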