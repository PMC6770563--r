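#' Univariate Cox screening of signature genes
#'
#' One Cox proportional-hazards fit per standardized gene (Breslow ties by
#' default; Efron behind the flag), reporting hazard ratios and Wald
#' p-values without multiplicity adjustment — a Benjamini-Hochberg column is
#' provided additionally. Degenerate (constant) genes are flagged, not
#' fatal.
#'
#' @param X Samples-by-genes expression matrix.
#' @param time,event Overall-survival time (years) and event indicator
#'   (1 = death observed).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return data.frame with gene, log_hr, hr, wald_p, bh_fdr, degenerate.
#' @export
univariateCoxScreen <- function(X, time, event, ties = "breslow") {
  if (sum(event) < 2) stopf("need at least 2 events")
  srv <- survival::Surv(time, event)
  rows <- lapply(colnames(X), function(g) {
    x <- X[, g]
    if (sd(x) < .Machine$double.eps)
      return(data.frame(gene = g, log_hr = NA_real_, hr = NA_real_,
                        wald_p = NA_real_, degenerate = TRUE))
    z <- as.numeric(scale(x))
    fit <- survival::coxph(srv ~ z, ties = ties)
    s <- summary(fit)
    data.frame(gene = g, log_hr = unname(coef(fit)),
               hr = unname(exp(coef(fit))),
               wald_p = s$coefficients[1, "Pr(>|z|)"], degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_fdr <- p.adjust(out$wald_p, method = "BH")
  out
}

# Event-stratified CV fold ids for survival models.
survFolds <- function(event, nFolds, seed) {
  withSeed(seed, {
    foldid <- integer(length(event))
    for (e in unique(event)) {
      idx <- which(event == e)
      foldid[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    foldid
  })
}

# Breslow cumulative baseline hazard (for linear predictor 0) on the
# training data.
breslowBaseline <- function(time, event, lp) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; elp <- exp(lp[ord])
  eventTimes <- sort(unique(time[event == 1]))
  haz <- vapply(eventTimes, function(t) {
    sum(event == 1 & time == t) / sum(elp[time >= t])
  }, numeric(1))
  list(time = eventTimes, cumhaz = cumsum(haz))
}

#' Ridge- (or lasso-) penalized Cox model on signature genes
#'
#' Maximizes the penalized partial log-likelihood (Breslow ties, as glmnet
#' implements) with the penalty strength chosen by k-fold cross-validation
#' of the partial-likelihood deviance; the Breslow cumulative baseline
#' hazard is estimated on the training data so per-sample survival curves
#' `S(t|x) = exp(-H0(t) exp(eta))` are available.
#'
#' @param X Samples-by-genes matrix.
#' @param time,event Survival outcome.
#' @param nFolds CV folds (default 10, event-stratified).
#' @param seed Fold-assignment seed.
#' @param penalty `"ridge"` (default) or `"lasso"`.
#' @param lambda Optional fixed penalty (skips CV).
#' @return A [CoxSignatureModel-class].
#' @export
fitRidgeCox <- function(X, time, event, nFolds = 10L, seed = 1L,
                        penalty = c("ridge", "lasso"), lambda = NULL) {
  penalty <- match.arg(penalty)
  alpha <- if (penalty == "ridge") 0 else 1
  srv <- survival::Surv(time, event)
  # glmnet needs >= 2 columns; a zero dummy is inert under standardization
  padded <- ncol(X) == 1
  if (padded) X <- cbind(X, `..pad..` = 0)
  if (is.null(lambda)) {
    foldid <- survFolds(event, nFolds, seed)
    cv <- glmnet::cv.glmnet(X, srv, family = "cox", alpha = alpha,
                            foldid = foldid)
    lambda <- cv$lambda.min
    beta <- as.numeric(coef(cv, s = "lambda.min"))
  } else {
    # refit with the target lambda embedded in the path so no
    # interpolation (or exact-refit call reconstruction) is needed
    fit0 <- glmnet::glmnet(X, srv, family = "cox", alpha = alpha)
    lam <- sort(unique(c(fit0$lambda, lambda * c(100, 10, 1))),
                decreasing = TRUE)
    fit <- glmnet::glmnet(X, srv, family = "cox", alpha = alpha,
                          lambda = lam)
    beta <- as.numeric(coef(fit, s = lambda))
  }
  names(beta) <- colnames(X)
  if (padded) {
    beta <- beta[colnames(X) != "..pad.."]
    X <- X[, colnames(X) != "..pad..", drop = FALSE]
  }
  lp <- as.numeric(X %*% beta)
  bl <- breslowBaseline(time, event, lp)
  methods::new("CoxSignatureModel", coefficients = beta, penalty = penalty,
               lambda = lambda, baselineTime = bl$time,
               baselineHazard = bl$cumhaz, nullModel = FALSE)
}

#' Null survival model: the training-set Kaplan-Meier
#'
#' The no-genomic-information comparison baseline: every sample receives
#' the training Kaplan-Meier curve.
#'
#' @param time,event Training survival outcome.
#' @return A [CoxSignatureModel-class] with `nullModel = TRUE`.
#' @export
fitNullSurvival <- function(time, event) {
  km <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- km$n.event > 0
  surv <- km$surv[keep]
  methods::new("CoxSignatureModel", coefficients = numeric(0),
               penalty = "none", lambda = 0, baselineTime = km$time[keep],
               baselineHazard = -log(pmax(surv, 1e-300)), nullModel = TRUE)
}

#' Per-sample survival probabilities from a fitted model
#'
#' @param model A [CoxSignatureModel-class].
#' @param X Samples-by-genes matrix (ignored for the null model).
#' @param times Evaluation times.
#' @return Matrix, samples x times, of S(t|x).
#' @export
predictSurvival <- function(model, X, times) {
  H0 <- if (length(model@baselineTime))
    approx(model@baselineTime, model@baselineHazard, xout = times,
           method = "constant", yleft = 0, rule = 2, f = 0)$y
  else rep(0, length(times))
  if (model@nullModel) {
    n <- if (is.null(dim(X))) length(X) else nrow(X)
    return(matrix(exp(-H0), n, length(times), byrow = TRUE))
  }
  genes <- names(model@coefficients)
  missing <- setdiff(genes, colnames(X))
  if (length(missing))
    stopf("matrix lacks model genes: %s", paste(missing, collapse = ", "))
  lp <- as.numeric(X[, genes, drop = FALSE] %*% model@coefficients)
  outer(exp(lp), H0, function(r, h) exp(-h * r))
}

#' Bootstrap-Lasso ("Boot Lasso") gene selection for survival
#'
#' Draws B bootstrap resamples (with replacement, size n) of the training
#' set, runs a lasso Cox with a per-bootstrap CV-chosen penalty on each,
#' retains the genes with nonzero coefficients in at least
#' `retainFraction` of the resamples, and refits a ridge Cox on the
#' retained set. An empty retained set yields the null-predictor model,
#' flagged.
#'
#' @param X Samples-by-genes matrix.
#' @param time,event Survival outcome.
#' @param B Bootstrap resamples (paper value 200).
#' @param retainFraction Retention threshold (paper value 0.5).
#' @param seed Integer seed.
#' @param cvFolds Folds for the per-bootstrap (and final ridge) CV.
#' @return A [BootLassoResult-class].
#' @export
bootLassoCox <- function(X, time, event, B = 200L, retainFraction = 0.5,
                         seed = 1L, cvFolds = 10L) {
  n <- nrow(X)
  counts <- setNames(numeric(ncol(X)), colnames(X))
  withSeed(seed, {
    for (b in seq_len(B)) {
      repeat {  # resamples must support CV: at least one event per fold
        idx <- sample.int(n, n, replace = TRUE)
        if (sum(event[idx]) >= max(3, cvFolds)) break
      }
      cv <- glmnet::cv.glmnet(X[idx, , drop = FALSE],
                              survival::Surv(time[idx], event[idx]),
                              family = "cox", alpha = 1, nfolds = cvFolds)
      # parsimonious CV rule: within one SE of the minimum; under a global
      # null this keeps the per-bootstrap supports (and hence the retained
      # set) essentially empty, as Bolasso-style selection intends
      beta <- as.numeric(coef(cv, s = "lambda.1se"))
      counts[beta != 0] <- counts[beta != 0] + 1
    }
  })
  retained <- names(counts)[counts / B >= retainFraction]
  if (length(retained)) {
    final <- fitRidgeCox(X[, retained, drop = FALSE], time, event,
                         nFolds = cvFolds, seed = seed)
    empty <- FALSE
  } else {
    final <- fitNullSurvival(time, event)
    empty <- TRUE
  }
  methods::new("BootLassoResult", B = as.integer(B),
               selectionCount = counts, retainedSet = retained,
               retainFraction = retainFraction, finalModel = final,
               emptySet = empty)
}

# Censoring-distribution Kaplan-Meier evaluated right-continuously at u
# (and at u- via `left = TRUE`).
censoringKM <- function(time, event) {
  km <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  list(time = km$time, surv = km$surv)
}

evalKM <- function(km, u, left = FALSE) {
  idx <- findInterval(u, km$time, left.open = left)
  c(1, km$surv)[idx + 1]
}

#' IPCW Brier score at one time point
#'
#' `BS(t) = (1/n) sum_i [ S(t|x_i)^2 1(T_i <= t, d_i = 1) / G(T_i-) +
#' (1 - S(t|x_i))^2 1(T_i > t) / G(t) ]`, where G is the Kaplan-Meier
#' estimate of the censoring distribution on the evaluation data; samples
#' censored before t contribute 0. An inverse weight below 1e-8 raises an
#' error naming the time.
#'
#' @param time,event Observed follow-up and event indicator.
#' @param predictedSurvival S(t|x_i), one probability per sample.
#' @param t Evaluation time.
#' @param G Optional precomputed censoring KM (from `censoringKM`).
#' @return The Brier score at t.
#' @export
brierScore <- function(time, event, predictedSurvival, t, G = NULL) {
  if (any(predictedSurvival < -1e-12 | predictedSurvival > 1 + 1e-12))
    stopf("predicted survival probabilities must lie in [0, 1]")
  if (is.null(G)) G <- censoringKM(time, event)
  n <- length(time)
  contrib <- numeric(n)
  dead <- time <= t & event == 1
  alive <- time > t
  if (any(dead)) {
    w <- evalKM(G, time[dead], left = TRUE)
    if (any(w < 1e-8))
      stopf("censoring-survival weight vanishes before t = %g", t)
    contrib[dead] <- predictedSurvival[dead]^2 / w
  }
  if (any(alive)) {
    gt <- evalKM(G, t)
    if (gt < 1e-8)
      stopf("censoring-survival weight vanishes at t = %g", t)
    contrib[alive] <- (1 - predictedSurvival[alive])^2 / gt
  }
  mean(contrib)
}

# Evaluation grid: 0, the observed times in (0, tMax], and tMax itself.
brierGrid <- function(time, tMax) {
  unique(c(0, sort(unique(time[time > 0 & time <= tMax])), tMax))
}

#' Integrated Brier score over a time grid
#'
#' Pointwise IPCW Brier scores on the observed-time grid restricted to
#' (0, tMax] (with 0 and tMax as quadrature endpoints) and their
#' trapezoidal time-average over \[0, tMax\].
#'
#' @param time,event Observed follow-up and event indicator.
#' @param survMatrix Samples x grid-times matrix of predicted S(t|x).
#' @param gridTimes Grid the columns of `survMatrix` correspond to
#'   (from `brierGrid` when omitted and the matrix matches).
#' @param tMax Upper integration limit in years (default 3).
#' @param modelLabel Label stored on the curve.
#' @return A [PredictionErrorCurve-class].
#' @export
integratedBrier <- function(time, event, survMatrix, gridTimes,
                            tMax = 3, modelLabel = "full_signature") {
  stopifnot(ncol(survMatrix) == length(gridTimes))
  G <- censoringKM(time, event)
  n <- length(time)
  wLeft <- evalKM(G, time, left = TRUE)   # G(T_i-), same at every t
  Gt <- evalKM(G, gridTimes)
  bs <- vapply(seq_along(gridTimes), function(j) {
    t <- gridTimes[j]; S <- survMatrix[, j]
    dead <- time <= t & event == 1
    alive <- time > t
    if (any(dead) && any(wLeft[dead] < 1e-8))
      stopf("censoring-survival weight vanishes before t = %g", t)
    if (any(alive) && Gt[j] < 1e-8)
      stopf("censoring-survival weight vanishes at t = %g", t)
    (sum(S[dead]^2 / wLeft[dead]) +
       sum((1 - S[alive])^2) / Gt[j]) / n
  }, numeric(1))
  ibsVal <- if (length(gridTimes) > 1) {
    dt <- diff(gridTimes)
    sum((bs[-1] + bs[-length(bs)]) / 2 * dt) / tMax
  } else bs
  methods::new("PredictionErrorCurve", times = gridTimes, brier = bs,
               ibs = ibsVal, tMax = tMax, modelLabel = modelLabel)
}

#' Prediction-error curve of a fitted survival model
#'
#' @param model A [CoxSignatureModel-class].
#' @param X Samples-by-genes matrix for the evaluation samples.
#' @param time,event Evaluation outcome.
#' @param tMax Upper limit in years (default 3).
#' @param modelLabel Curve label.
#' @return A [PredictionErrorCurve-class].
#' @export
predictionErrorCurve <- function(model, X, time, event, tMax = 3,
                                 modelLabel = "full_signature") {
  grid <- brierGrid(time, tMax)
  sv <- predictSurvival(model, X, grid)
  integratedBrier(time, event, sv, grid, tMax = tMax,
                  modelLabel = modelLabel)
}

#' Cross-validated prediction error of survival models
#'
#' Out-of-fold survival predictions are pooled over the k folds, then a
#' single Brier/IBS computation is run on the pooled predictions — one
#' curve per requested model specification.
#'
#' @param X Samples-by-genes matrix.
#' @param time,event Survival outcome.
#' @param models Subset of `c("null", "full_signature", "boot_lasso")`.
#' @param nFolds CV folds (default 10; `nFolds = n` gives leave-one-out).
#' @param seed Integer seed (folds and inner tuning).
#' @param tMax Upper limit in years.
#' @param B,retainFraction,cvFolds Boot-Lasso parameters (see
#'   [bootLassoCox()]).
#' @return Named list of [PredictionErrorCurve-class] objects.
#' @export
cvPredictionError <- function(X, time, event,
                              models = c("null", "full_signature"),
                              nFolds = 10L, seed = 1L, tMax = 3,
                              B = 200L, retainFraction = 0.5,
                              cvFolds = 10L) {
  models <- match.arg(models, c("null", "full_signature", "boot_lasso"),
                      several.ok = TRUE)
  n <- nrow(X)
  foldid <- survFolds(event, nFolds, seed)
  grid <- brierGrid(time, tMax)
  pooled <- lapply(models, function(m) matrix(NA_real_, n, length(grid)))
  names(pooled) <- models
  for (k in seq_len(nFolds)) {
    trIdx <- which(foldid != k); teIdx <- which(foldid == k)
    if (!length(teIdx)) next
    for (m in models) {
      fit <- switch(m,
        null = fitNullSurvival(time[trIdx], event[trIdx]),
        full_signature = fitRidgeCox(X[trIdx, , drop = FALSE],
                                     time[trIdx], event[trIdx],
                                     nFolds = cvFolds, seed = seed + k),
        boot_lasso = bootLassoCox(X[trIdx, , drop = FALSE], time[trIdx],
                                  event[trIdx], B = B,
                                  retainFraction = retainFraction,
                                  seed = seed + k,
                                  cvFolds = cvFolds)@finalModel)
      pooled[[m]][teIdx, ] <- predictSurvival(fit, X[teIdx, , drop = FALSE],
                                              grid)
    }
  }
  lapply(setNames(models, models), function(m)
    integratedBrier(time, event, pooled[[m]], grid, tMax = tMax,
                    modelLabel = m))
}

#' Conditional Kaplan-Meier curves along a signature
#'
#' Nearest-neighbor (rectangular-kernel) Kaplan-Meier estimates around the
#' smallest, median and largest signature value: each anchor's neighborhood
#' is the `ceiling(span * n)` samples closest in signature value (ties by
#' sample order), labelled low / medium / high.
#'
#' @param signatureValues Per-sample linear predictor.
#' @param time,event Survival outcome.
#' @param span Neighborhood fraction in (0, 1\]; `span * n >= 2` required.
#' @return Named list (low, medium, high) of data.frames with columns
#'   time, surv, n_risk, n_event.
#' @export
conditionalKM <- function(signatureValues, time, event, span = 0.25) {
  n <- length(signatureValues)
  m <- ceiling(span * n)
  if (m < 2) stopf("span * n must be at least 2")
  anchors <- c(low = min(signatureValues),
               medium = median(signatureValues),
               high = max(signatureValues))
  lapply(anchors, function(a) {
    nb <- order(abs(signatureValues - a), seq_len(n))[seq_len(m)]
    km <- survival::survfit(survival::Surv(time[nb], event[nb]) ~ 1)
    keep <- km$n.event > 0  # the survival step function changes only here
    data.frame(time = km$time[keep], surv = km$surv[keep],
               n_risk = km$n.risk[keep], n_event = km$n.event[keep])
  })
}

# Survival probability of a KM curve data.frame at time t.
kmAt <- function(kmdf, t) {
  idx <- which(kmdf$time <= t)
  if (!length(idx)) 1 else kmdf$surv[max(idx)]
}

#' Maximally selected log-rank cut point
#'
#' Evaluates the standardized two-group log-rank statistic at every
#' observed cut whose quantile lies within the epsilon range, takes the
#' maximum absolute value M, and adjusts for the multiplicity of cuts with
#' the Brownian-bridge improved-Bonferroni approximation
#' `p ~ 4 phi(b)/b + phi(b)(b - 1/b) log(e2(1-e1)/(e1(1-e2)))`, capped at 1
#' and floored at the pointwise two-sided normal p. A single candidate cut
#' reduces to the pointwise p exactly.
#'
#' @param values Per-sample predictor (e.g., the signature value).
#' @param time,event Survival outcome; at least 10 samples and 5 events.
#' @param epsilon Quantile search bounds (default 0.1, 0.9).
#' @return A [CutpointResult-class].
#' @export
maxstatCutpoint <- function(values, time, event, epsilon = c(0.1, 0.9)) {
  n <- length(values)
  if (n < 10) stopf("need at least 10 samples")
  if (sum(event) < 5) stopf("need at least 5 events")
  vs <- sort(unique(values))
  if (length(vs) < 2) stopf("all predictor values identical")
  quant <- vapply(vs, function(c) mean(values <= c), numeric(1))
  cand <- which(quant >= epsilon[1] - 1e-12 & quant <= epsilon[2] + 1e-12 &
                  quant < 1)
  if (!length(cand)) stopf("no candidate cut inside the epsilon range")
  cuts <- vs[cand]

  ord <- order(values, seq_len(n))
  vSorted <- values[ord]
  cutPos <- vapply(cuts, function(c) sum(vSorted <= c), integer(1))
  eventTimes <- sort(unique(time[event == 1]))
  U <- numeric(length(cuts)); V <- numeric(length(cuts))
  for (t in eventTimes) {
    atRisk <- time >= t
    dying <- time == t & event == 1
    nt <- sum(atRisk); dt <- sum(dying)
    if (nt < 2) next
    n1 <- cumsum(atRisk[ord])[cutPos]
    d1 <- cumsum(dying[ord])[cutPos]
    U <- U + d1 - dt * n1 / nt
    V <- V + dt * (n1 / nt) * (1 - n1 / nt) * (nt - dt) / (nt - 1)
  }
  Z <- ifelse(V > 0, U / sqrt(V), 0)
  best <- which.max(abs(Z))
  M <- abs(Z[best])
  pPoint <- 2 * pnorm(-M)
  pAdj <- if (length(cuts) == 1) pPoint else {
    e1 <- epsilon[1]; e2 <- epsilon[2]
    if (M <= 1) 1 else {
      approxP <- 4 * dnorm(M) / M +
        dnorm(M) * (M - 1 / M) * log((e2 * (1 - e1)) / (e1 * (1 - e2)))
      min(1, max(approxP, pPoint))
    }
  }
  methods::new("CutpointResult", cutValue = cuts[best],
               cutQuantile = quant[cand[best]], maxStatistic = M,
               adjustedP = pAdj, epsilon = epsilon)
}
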