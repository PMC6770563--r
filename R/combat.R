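#' Empirical-Bayes location/scale batch adjustment
#'
#' Parametric ComBat-style adjustment used to merge expression datasets
#' before cross-dataset classification. Each gene is standardized (grand
#' mean and pooled variance removed, retained covariate effects taken out),
#' per-batch location (gamma) and scale (delta^2) effects are estimated,
#' shrunk toward parametric priors fitted across genes by the method of
#' moments (normal prior for gamma, inverse-gamma for delta^2) through the
#' coupled empirical-Bayes fixed-point updates, and the data are
#' back-transformed with the shrunk estimates.
#'
#' For the external-validation scenario the subtype label is *not* supplied
#' as a covariate (labels are unknown at prediction time); pass it via
#' `covariates` when adjusting within a labelled cohort.
#'
#' @param x [ExpressionMatrix-class] or plain genes-x-samples matrix.
#' @param batch Batch labels, one per sample; at least 2 batches with at
#'   least 2 samples each.
#' @param covariates Optional design matrix (samples x covariates) of
#'   effects to retain; must not be confounded with batch.
#' @param conv Fixed-point relative-change tolerance (default 1e-6).
#' @param maxIter Maximum fixed-point iterations (default 5000).
#' @return list with `adjusted` (same class as the input expression values)
#'   and `params` ([ComBatParams-class]).
#' @export
combatAdjust <- function(x, batch, covariates = NULL, conv = 1e-6,
                         maxIter = 5000L) {
  em <- NULL
  if (methods::is(x, "ExpressionMatrix")) { em <- x; x <- exprValues(x) }
  batch <- factor(batch)
  if (length(batch) != ncol(x)) stopf("batch labels misaligned with samples")
  if (nlevels(batch) < 2) stopf("need at least 2 batches")
  nPer <- table(batch)
  if (any(nPer < 2)) stopf("batch(es) with fewer than 2 samples: %s",
                           paste(names(nPer)[nPer < 2], collapse = ", "))
  batchmod <- model.matrix(~ -1 + batch)
  design <- batchmod
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    design <- cbind(batchmod, covariates)
    if (qr(design)$rank < ncol(design))
      stopf("covariates confounded with batch")
  }
  G <- nrow(x); n <- ncol(x); nb <- nlevels(batch)

  bHat <- solve(crossprod(design), crossprod(design, t(x)))
  grandMean <- as.numeric(crossprod(nPer / n, bHat[seq_len(nb), , drop = FALSE]))
  resid <- x - t(design %*% bHat)
  varPooled <- rowSums(resid^2) / n
  if (any(varPooled <= 0))
    stopf("gene(s) with zero pooled variance cannot be adjusted")

  standMean <- matrix(grandMean, G, n)
  covCoef <- matrix(numeric(0), 0, 0)
  if (!is.null(covariates)) {
    tmp <- design; tmp[, seq_len(nb)] <- 0
    standMean <- standMean + t(tmp %*% bHat)
    covCoef <- t(bHat[-seq_len(nb), , drop = FALSE])
  }
  sData <- (x - standMean) / sqrt(varPooled)

  gammaHat <- sapply(levels(batch), function(b)
    rowMeans(sData[, batch == b, drop = FALSE]))
  delta2Hat <- sapply(levels(batch), function(b)
    apply(sData[, batch == b, drop = FALSE], 1, var))
  gammaBar <- colMeans(gammaHat)
  tau2 <- apply(gammaHat, 2, var)
  m <- colMeans(delta2Hat); s2 <- apply(delta2Hat, 2, var)
  aPrior <- (2 * s2 + m^2) / s2
  bPrior <- (m * s2 + m^3) / s2

  gammaStar <- gammaHat; delta2Star <- delta2Hat
  iterations <- 0L
  for (b in seq_len(nb)) {
    idx <- batch == levels(batch)[b]
    nB <- sum(idx)
    gOld <- gammaHat[, b]; dOld <- delta2Hat[, b]
    it <- 0L
    repeat {
      it <- it + 1L
      gNew <- (nB * tau2[b] * gammaHat[, b] + dOld * gammaBar[b]) /
        (nB * tau2[b] + dOld)
      sum2 <- rowSums((sData[, idx, drop = FALSE] - gNew)^2)
      dNew <- (0.5 * sum2 + bPrior[b]) / (nB / 2 + aPrior[b] - 1)
      change <- max(abs(gNew - gOld) / pmax(abs(gOld), 1e-12),
                    abs(dNew - dOld) / dOld)
      gOld <- gNew; dOld <- dNew
      if (change < conv) break
      if (it >= maxIter)
        stopf("EB fixed point did not converge after %d iterations (last change %.3g)",
              maxIter, change)
    }
    gammaStar[, b] <- gOld; delta2Star[, b] <- dOld
    iterations <- max(iterations, it)
  }

  adjusted <- sData
  for (b in seq_len(nb)) {
    idx <- batch == levels(batch)[b]
    adjusted[, idx] <- (sData[, idx, drop = FALSE] - gammaStar[, b]) /
      sqrt(delta2Star[, b])
  }
  adjusted <- adjusted * sqrt(varPooled) + standMean

  params <- methods::new("ComBatParams",
    gammaHat = gammaHat, gammaStar = gammaStar,
    delta2Hat = delta2Hat, delta2Star = delta2Star,
    gammaBar = gammaBar, tau2 = tau2, aPrior = aPrior, bPrior = bPrior,
    alphaHat = setNames(grandMean, rownames(x)), sigma2Hat = varPooled,
    covariateCoef = covCoef, batches = levels(batch),
    iterations = iterations)

  out <- if (!is.null(em))
    methods::new("ExpressionMatrix", values = adjusted,
                 transform = em@transform, pseudocount = em@pseudocount,
                 effectiveLibsizes = em@effectiveLibsizes)
  else adjusted
  list(adjusted = out, params = params)
}

#' Dump batch-adjustment parameters as JSON for audit
#'
#' @param params A [ComBatParams-class].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
writeComBatParams <- function(params, path) {
  jsonlite::write_json(list(
    batches = params@batches,
    gamma_bar = params@gammaBar, tau2 = params@tau2,
    a_prior = params@aPrior, b_prior = params@bPrior,
    iterations = params@iterations,
    gamma_hat = as.data.frame(params@gammaHat),
    gamma_star = as.data.frame(params@gammaStar),
    delta2_hat = as.data.frame(params@delta2Hat),
    delta2_star = as.data.frame(params@delta2Star)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
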