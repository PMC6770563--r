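#' Observation-level precision weights (voom)
#'
#' log-CPM transform (prior 0.5) with per-observation precision weights
#' from the fitted mean-variance trend: a locally weighted regression
#' (span 0.5) of the square-root residual standard deviation on average
#' log-count, interpolated at each observation's fitted log-count, with
#' weight = predicted-sd^-4. Delegates to limma's voom implementation.
#'
#' @param counts Count matrix (genes x samples) or [UBCCohort-class].
#' @param design Model matrix, or a factor/character vector of group
#'   labels (converted to `~ group`); at least 2 samples per group.
#' @param span Lowess span for the trend (default 0.5).
#' @return list with `expr` (an [ExpressionMatrix-class], log-CPM) and
#'   `weights` (matrix, genes x samples) and `design`.
#' @export
voomWeights <- function(counts, design, span = 0.5) {
  if (methods::is(counts, "UBCCohort")) counts <- cohortCounts(counts)
  if (!is.matrix(design)) {
    grp <- factor(design)
    if (any(table(grp) < 2)) stopf("need at least 2 samples per group")
    design <- model.matrix(~grp)
  }
  v <- limma::voom(counts, design, span = span)
  em <- methods::new("ExpressionMatrix", values = v$E,
                     transform = "log_cpm", pseudocount = 0.5,
                     effectiveLibsizes = colSums(counts))
  list(expr = em, weights = v$weights, design = design)
}

# Newton inversion of the trigamma function (solve trigamma(x) = y).
trigammaInverse <- function(y) {
  vapply(y, function(yi) {
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

# Moment-matching fit of the scaled-F prior on gene variances: returns the
# prior df d0 and prior variance s0^2 from log-variance moments
# (digamma/trigamma inversion).
fitVariancePrior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  z <- log(s2[ok]); dfok <- df[ok]
  e <- z - digamma(dfok / 2) + log(dfok / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(dfok / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigammaInverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(priorDf = d0, priorVar = s02)
}

#' Moderated t-test with empirical-Bayes variance shrinkage
#'
#' Weighted least squares per gene, then shrinkage of the residual
#' variances toward a common prior:
#' `s2_post = (d0 s0^2 + d_g s2_g) / (d0 + d_g)` with (d0, s0^2) estimated
#' by closed-form moment matching on the log variances; the moderated t is
#' referred to a t distribution on `d0 + d_g` degrees of freedom, with
#' Benjamini-Hochberg FDR across genes.
#'
#' @param expr Expression matrix (genes x samples) or
#'   [ExpressionMatrix-class] (e.g., the voom log-CPM).
#' @param design Model matrix (samples x coefficients) or group labels.
#' @param weights Optional observation weights (genes x samples), e.g.
#'   voom precision weights.
#' @param coefIndex Column of the design tested (default: last).
#' @param priorDf Force the prior df d0: `0` gives the ordinary per-gene
#'   t-test, `Inf` the normal reference with the pooled prior variance;
#'   NULL (default) estimates it.
#' @return list with `table` (gene, logFC, t, p_value, fdr, df_total),
#'   `priorDf`, `priorVar`, `residualDf`.
#' @export
moderatedTTest <- function(expr, design, weights = NULL, coefIndex = NULL,
                           priorDf = NULL) {
  if (methods::is(expr, "ExpressionMatrix")) expr <- exprValues(expr)
  if (!is.matrix(design)) design <- model.matrix(~ factor(design))
  if (is.null(coefIndex)) coefIndex <- ncol(design)
  G <- nrow(expr); n <- ncol(expr); p <- ncol(design)
  if (n - p < 1) stopf("residual df must be at least 1")
  if (is.null(weights)) weights <- matrix(1, G, n)

  beta <- numeric(G); v <- numeric(G); s2 <- numeric(G)
  for (g in seq_len(G)) {
    w <- weights[g, ]
    fit <- stats::lm.wfit(design, expr[g, ], w)
    xtwx <- crossprod(design * sqrt(w))
    vg <- solve(xtwx)[coefIndex, coefIndex]
    beta[g] <- fit$coefficients[coefIndex]
    v[g] <- vg
    s2[g] <- sum(w * fit$residuals^2) / fit$df.residual
  }
  dg <- rep(n - p, G)

  prior <- fitVariancePrior(s2, dg)
  if (!is.null(priorDf)) prior$priorDf <- priorDf
  d0 <- prior$priorDf; s02 <- prior$priorVar
  s2post <- if (is.infinite(d0)) rep(s02, G)
            else if (d0 == 0) s2
            else (d0 * s02 + dg * s2) / (d0 + dg)
  tstat <- beta / sqrt(s2post * v)
  dfTotal <- dg + d0
  pval <- 2 * pt(-abs(tstat), df = dfTotal)
  tab <- data.frame(gene = rownames(expr) %||% sprintf("g%d", seq_len(G)),
                    logFC = beta, t = tstat, p_value = pval,
                    fdr = p.adjust(pval, method = "BH"),
                    df_total = dfTotal)
  list(table = tab, priorDf = d0, priorVar = s02, residualDf = dg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Comparative-CT (delta-delta-CT) qPCR quantification
#'
#' Duplicate wells are averaged per sample and gene, the per-replicate
#' `dCT = CT_target - CT_reference` is formed, and for each gene and
#' non-control condition `ddCT = mean dCT(condition) - mean dCT(control)`
#' and `FC = 2^-ddCT`. Replicate dCT values are compared by a two-sample
#' Student t-test (pooled variance by default; Welch behind the flag) with
#' Benjamini-Hochberg FDR across genes within each condition.
#'
#' @param records data.frame with columns `sample`, `condition`, `gene`,
#'   `ct_target`, `ct_ref` (CT cycles in (0, 45); rows with a missing
#'   reference CT are rejected with a message).
#' @param controlCondition Label of the calibrator condition.
#' @param varEqual Pooled-variance Student t (default TRUE); FALSE gives
#'   Welch.
#' @return data.frame with gene, condition, mean_dct, ddct, fc, t_p, fdr.
#' @export
ddctQuantify <- function(records, controlCondition, varEqual = TRUE) {
  need <- c("sample", "condition", "gene", "ct_target", "ct_ref")
  if (!all(need %in% colnames(records)))
    stopf("records must have columns: %s", paste(need, collapse = ", "))
  bad <- is.na(records$ct_ref) | is.na(records$ct_target)
  if (any(bad)) {
    message(sum(bad), " record(s) rejected for missing CT values")
    records <- records[!bad, , drop = FALSE]
  }
  if (any(records$ct_target <= 0 | records$ct_target >= 45 |
          records$ct_ref <= 0 | records$ct_ref >= 45))
    stopf("CT values must lie in (0, 45)")
  if (!controlCondition %in% records$condition)
    stopf("control condition '%s' absent from the records", controlCondition)

  # average duplicate wells, then one dCT per sample x gene
  agg <- stats::aggregate(cbind(ct_target, ct_ref) ~ sample + condition + gene,
                          data = records, FUN = mean)
  agg$dct <- agg$ct_target - agg$ct_ref

  out <- NULL
  for (g in unique(agg$gene)) {
    sub <- agg[agg$gene == g, ]
    ctrl <- sub$dct[sub$condition == controlCondition]
    if (length(ctrl) < 2)
      stopf("gene %s: need >= 2 control replicates", g)
    for (cond in unique(sub$condition)) {
      trt <- sub$dct[sub$condition == cond]
      if (length(trt) < 2)
        stopf("gene %s, condition %s: need >= 2 replicates", g, cond)
      ddct <- mean(trt) - mean(ctrl)
      pv <- if (cond == controlCondition) NA_real_ else
        t.test(trt, ctrl, var.equal = varEqual)$p.value
      out <- rbind(out, data.frame(gene = g, condition = cond,
                                   mean_dct = mean(trt), ddct = ddct,
                                   fc = 2^(-ddct), t_p = pv))
    }
  }
  out$fdr <- NA_real_
  for (cond in setdiff(unique(out$condition), controlCondition)) {
    idx <- out$condition == cond
    out$fdr[idx] <- p.adjust(out$t_p[idx], method = "BH")
  }
  rownames(out) <- NULL
  out
}
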