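#' Extract a samples-by-genes signature matrix
#'
#' Convenience transpose/subset used by the classifier and survival stages:
#' rows become samples, columns the requested signature genes, in the
#' requested order.
#'
#' @param em [ExpressionMatrix-class] (genes x samples).
#' @param genes Character vector of gene ids; error on missing genes.
#' @return Numeric matrix, samples x genes.
#' @export
signatureMatrix <- function(em, genes) {
  vals <- exprValues(em)
  missing <- setdiff(genes, rownames(vals))
  if (length(missing))
    stopf("signature genes absent from the expression matrix: %s",
          paste(missing, collapse = ", "))
  t(vals[genes, , drop = FALSE])
}

#' Balanced (stratified) train/test split
#'
#' Randomly splits samples into training and test sets with the class
#' proportions preserved: each class contributes `round(proportion * n_c)`
#' training samples. Reproducible from the seed.
#'
#' @param labels Class labels named by sample id.
#' @param proportion Training fraction (default 0.7, the 70-30 split).
#' @param seed Integer seed.
#' @return list with `trainIds`, `testIds`, `proportion` and
#'   `stratumCounts` (train/test count per class).
#' @export
splitTrainTest <- function(labels, proportion = 0.7, seed = 1L) {
  if (is.null(names(labels))) names(labels) <- as.character(seq_along(labels))
  counts <- table(labels)
  if (any(counts < 2)) stopf("need at least 2 samples per class")
  withSeed(seed, {
    trainIds <- unlist(lapply(names(counts), function(cl) {
      ids <- names(labels)[labels == cl]
      sample(ids, round(proportion * length(ids)))
    }), use.names = FALSE)
    testIds <- setdiff(names(labels), trainIds)
    sc <- rbind(train = table(labels[trainIds])[names(counts)],
                test = table(factor(labels[testIds],
                                    levels = names(counts))))
    colnames(sc) <- names(counts)
    list(trainIds = trainIds, testIds = testIds, proportion = proportion,
         stratumCounts = sc)
  })
}

# Stratified CV fold assignment; errors when any fold would see one class.
stratifiedFolds <- function(y01, nFolds, seed) {
  withSeed(seed, {
    foldid <- integer(length(y01))
    for (cl in unique(y01)) {
      idx <- which(y01 == cl)
      foldid[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    tab <- table(foldid, y01)
    if (any(tab == 0))
      stopf("a CV fold contains a single class; reduce nFolds")
    foldid
  })
}

#' Elastic-net logistic subtype classifier with joint alpha/lambda CV
#'
#' Minimizes the penalized negative binomial log-likelihood
#' `-(1/n) loglik + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)` (genes
#' standardized internally, coefficients back-transformed) over an automatic
#' 100-value lambda path spanning four decades per alpha, and selects the
#' (alpha, lambda) pair minimizing the mean 10-fold cross-validated binomial
#' deviance; lambda ties break toward the larger (more parsimonious) value.
#'
#' @param X Samples-by-genes expression matrix over the signature genes.
#' @param y Binary class labels (character/factor), one per row of `X`.
#' @param alphaGrid Mixing-parameter grid (default 0, .25, .5, .75, 1).
#' @param nFolds CV folds (default 10, stratified).
#' @param seed Integer seed for the fold assignment.
#' @param positiveClass Label encoded as 1 (default `"basal"`).
#' @param fixedAlpha,fixedLambda Skip CV and fit at these frozen tuning
#'   parameters (used for external validation).
#' @return An [ElasticNetModel-class].
#' @export
fitElasticNetLogistic <- function(X, y, alphaGrid = c(0, 0.25, 0.5, 0.75, 1),
                                  nFolds = 10L, seed = 1L,
                                  positiveClass = "basal",
                                  fixedAlpha = NULL, fixedLambda = NULL) {
  if (ncol(X) == 0) stopf("empty gene set")
  y <- as.character(y)
  if (length(unique(y)) < 2) stopf("labels contain a single class")
  y01 <- as.integer(y == positiveClass)

  if (!is.null(fixedAlpha) && !is.null(fixedLambda)) {
    fit0 <- glmnet::glmnet(X, y01, family = "binomial",
                           alpha = fixedAlpha, nlambda = 100,
                           lambda.min.ratio = 1e-4)
    lam <- sort(unique(c(fit0$lambda, fixedLambda * c(100, 10, 1))),
                decreasing = TRUE)
    fit <- glmnet::glmnet(X, y01, family = "binomial", alpha = fixedAlpha,
                          lambda = lam)
    cf <- as.numeric(coef(fit, s = fixedLambda))
    return(methods::new("ElasticNetModel", intercept = cf[1],
                        coefficients = setNames(cf[-1], colnames(X)),
                        alpha = fixedAlpha, lambda = fixedLambda,
                        cvTable = data.frame(), positiveClass = positiveClass))
  }

  foldid <- stratifiedFolds(y01, nFolds, seed)
  cvTable <- NULL; best <- NULL
  for (a in alphaGrid) {
    cv <- glmnet::cv.glmnet(X, y01, family = "binomial", alpha = a,
                            foldid = foldid, type.measure = "deviance",
                            nlambda = 100, lambda.min.ratio = 1e-4)
    cvTable <- rbind(cvTable, data.frame(alpha = a, lambda = cv$lambda,
                                         cv_deviance = cv$cvm))
    i <- which.min(cv$cvm)  # lambda descending: first min = largest lambda
    cand <- list(alpha = a, lambda = cv$lambda[i], cvm = cv$cvm[i], fit = cv)
    if (is.null(best) || cand$cvm < best$cvm - 1e-12 ||
        (abs(cand$cvm - best$cvm) <= 1e-12 && cand$lambda > best$lambda))
      best <- cand
  }
  cf <- as.numeric(coef(best$fit, s = best$lambda))
  methods::new("ElasticNetModel", intercept = cf[1],
               coefficients = setNames(cf[-1], colnames(X)),
               alpha = best$alpha, lambda = best$lambda, cvTable = cvTable,
               positiveClass = positiveClass)
}

#' Predicted positive-class probabilities from an elastic-net model
#'
#' @param model An [ElasticNetModel-class].
#' @param X Samples-by-genes matrix; columns are matched to the training
#'   gene order by name (error on missing genes).
#' @return Numeric vector of probabilities for the positive class.
#' @export
predictProb <- function(model, X) {
  genes <- names(model@coefficients)
  missing <- setdiff(genes, colnames(X))
  if (length(missing))
    stopf("test matrix lacks training genes: %s",
          paste(missing, collapse = ", "))
  eta <- model@intercept +
    as.numeric(X[, genes, drop = FALSE] %*% model@coefficients)
  1 / (1 + exp(-eta))
}

# ClassifierMetrics from a 2x2 confusion table (predicted x truth,
# positive class first in both dimensions).
confusionMetrics <- function(confusion, ciMethod = "clopper-pearson",
                             probs = NULL, yTest = NULL, nBoot = 2000L,
                             seed = 1L) {
  n <- sum(confusion)
  correct <- sum(diag(confusion))
  tp <- confusion[1, 1]; fn <- confusion[2, 1]
  tn <- confusion[2, 2]; fp <- confusion[1, 2]
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ci <- if (ciMethod == "clopper-pearson") {
    as.numeric(binom.test(correct, n)$conf.int)
  } else {
    stopifnot(!is.null(probs), !is.null(yTest))
    hits <- (probs > 0.5) == yTest
    withSeed(seed, {
      accs <- replicate(nBoot, mean(sample(hits, n, replace = TRUE)))
      as.numeric(quantile(accs, c(0.025, 0.975)))
    })
  }
  methods::new("ClassifierMetrics", accuracy = correct / n,
               sensitivity = sens, specificity = spec, accuracyCI = ci,
               confusion = confusion, ciMethod = ciMethod)
}

#' Evaluate a fitted classifier on a test set
#'
#' Predictions at probability threshold 0.5; accuracy confidence interval by
#' the exact Clopper-Pearson binomial interval (a bootstrap percentile
#' interval is available as an option).
#'
#' @param model An [ElasticNetModel-class].
#' @param XTest,yTest Test expression (samples x genes) and labels.
#' @param ciMethod `"clopper-pearson"` (default) or `"bootstrap"`.
#' @param nBoot Bootstrap replicates when `ciMethod = "bootstrap"`.
#' @param seed Seed for the bootstrap CI.
#' @return A [ClassifierMetrics-class].
#' @export
evaluateClassifier <- function(model, XTest, yTest,
                               ciMethod = "clopper-pearson",
                               nBoot = 2000L, seed = 1L) {
  pos <- model@positiveClass
  probs <- predictProb(model, XTest)
  predPos <- probs > 0.5
  truthPos <- as.character(yTest) == pos
  confusion <- matrix(c(sum(predPos & truthPos), sum(!predPos & truthPos),
                        sum(predPos & !truthPos), sum(!predPos & !truthPos)),
                      2, 2,
                      dimnames = list(predicted = c(pos, paste0("not_", pos)),
                                      truth = c(pos, paste0("not_", pos))))
  confusionMetrics(confusion, ciMethod = ciMethod, probs = probs,
                   yTest = truthPos, nBoot = nBoot, seed = seed)
}

#' Stability-path gene selection
#'
#' Draws class-stratified half-samples without replacement; on each, runs
#' the lasso path and records the first q genes to enter, where q is the
#' largest integer satisfying the per-comparison error bound
#' `q^2 / ((2 pi - 1) p) <= pcer * p`. A gene's selection frequency is the
#' fraction of subsamples in which it was among the first q; the stable set
#' is thresholded at pi.
#'
#' @param X Samples-by-genes matrix.
#' @param y Binary labels.
#' @param piThreshold Stability threshold pi (default 0.8).
#' @param pcer Per-comparison error rate (default 0.1).
#' @param nSubsamples Number of half-sample draws (default 100).
#' @param seed Integer seed.
#' @param positiveClass Label encoded as 1.
#' @return A [StabilitySelectionResult-class].
#' @export
stabilityPathSelect <- function(X, y, piThreshold = 0.8, pcer = 0.1,
                                nSubsamples = 100L, seed = 1L,
                                positiveClass = "basal") {
  p <- ncol(X)
  y <- as.character(y)
  if (any(table(y) < 4)) stopf("need at least 4 samples per class")
  q <- floor(sqrt(pcer * (2 * piThreshold - 1)) * p + 1e-9)
  if (q < 1)
    stopf("error bound gives q = 0; increase pcer or reduce the gene set")
  q <- min(q, p)
  y01 <- as.integer(y == positiveClass)
  counts <- setNames(numeric(p), colnames(X))
  withSeed(seed, {
    for (s in seq_len(nSubsamples)) {
      idx <- unlist(lapply(unique(y01), function(cl) {
        cls <- which(y01 == cl)
        sample(cls, floor(length(cls) / 2))
      }), use.names = FALSE)
      fit <- glmnet::glmnet(X[idx, , drop = FALSE], y01[idx],
                            family = "binomial", alpha = 1,
                            nlambda = 100, dfmax = q + 5L)
      beta <- as.matrix(fit$beta)
      entry <- apply(beta != 0, 1, function(r) {
        w <- which(r); if (length(w)) w[1] else Inf
      })
      entered <- which(is.finite(entry))
      if (!length(entered)) next
      mag <- vapply(entered, function(g) abs(beta[g, entry[g]]), numeric(1))
      ord <- entered[order(entry[entered], -mag)]
      counts[ord[seq_len(min(q, length(ord)))]] <-
        counts[ord[seq_len(min(q, length(ord)))]] + 1
    }
  })
  freq <- counts / nSubsamples
  methods::new("StabilitySelectionResult", selectionFrequency = freq,
               stableSet = names(freq)[freq >= piThreshold],
               piThreshold = piThreshold, pcer = pcer, q = as.integer(q),
               nSubsamples = as.integer(nSubsamples))
}

#' External validation of the subtype classifier
#'
#' Fits the elastic net on dataset A (joint alpha/lambda CV unless frozen
#' tuning parameters are supplied) and reports metrics on dataset B. Batch
#' adjustment of the merged expression matrix (see [combatAdjust()]) is the
#' caller's responsibility and should precede this step.
#'
#' @param XTrain,yTrain Training dataset (samples x genes, labels).
#' @param XTest,yTest External dataset evaluated with the frozen model.
#' @param ... Passed to [fitElasticNetLogistic()].
#' @return list with `model` and `metrics`.
#' @export
externalValidation <- function(XTrain, yTrain, XTest, yTest, ...) {
  model <- fitElasticNetLogistic(XTrain, yTrain, ...)
  list(model = model, metrics = evaluateClassifier(model, XTest, yTest))
}
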