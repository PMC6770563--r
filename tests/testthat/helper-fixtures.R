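# Small fixtures built in code at test time.

# Plain count matrix with gene names.
toyCounts <- function() {
  cnt <- cbind(s1 = c(100, 200, 300, 400, 500),
               s2 = c(110, 190, 310, 390, 5000))
  rownames(cnt) <- paste0("g", 1:5)
  cnt
}

# Mixed-censoring survival fixture, n = 8.
toySurv <- function() {
  list(time = c(0.5, 1.2, 1.4, 2.0, 2.5, 3.1, 3.5, 4.0),
       event = c(1, 0, 1, 1, 0, 1, 0, 1))
}

# Small logistic problem that is NOT separable (finite MLE exists).
toyLogistic <- function(seed = 42) {
  set.seed(seed)
  n <- 80
  X <- cbind(gA = rnorm(n), gB = rnorm(n))
  eta <- 0.8 * X[, 1] - 0.5 * X[, 2]
  y <- ifelse(runif(n) < plogis(eta), "basal", "luminal")
  # guard against accidental separation
  stopifnot(min(table(y)) > 10)
  list(X = X, y = y)
}

# Expression + survival cohort for the survival-model tests.
survCohort <- function(seed, n = 300, betas = c(g0001 = 1, g0002 = 0.7,
                                                g0003 = -0.7),
                       nGenes = 60, censoring = 0.3) {
  co <- generateCohort(syntheticConfig(
    nSamples = n, nGenes = nGenes, nSignatureGenes = 0,
    coxBetas = betas, targetCensoring = censoring, seed = seed))
  ann <- as.data.frame(SummarizedExperiment::colData(co))
  em <- logCPM(co)
  list(cohort = co, X = t(exprValues(em)), time = ann$os_time,
       event = ann$os_event, ann = ann)
}
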