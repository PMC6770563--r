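test_that("univariate Cox screen: recovery, null uniformity, degeneracy", {
  fx <- survCohort(seed = 71, n = 300, betas = c(g0001 = 1), nGenes = 40)
  scr <- univariateCoxScreen(fx$X, fx$time, fx$event)
  expect_lt(abs(scr$log_hr[scr$gene == "g0001"] - 1), 0.25)
  expect_true(all(c("wald_p", "bh_fdr") %in% colnames(scr)))
  expect_true(all(scr$bh_fdr >= scr$wald_p - 1e-12, na.rm = TRUE))

  # constant gene flagged, not fatal
  Xd <- cbind(fx$X[, 1:3], flat = rep(2, nrow(fx$X)))
  scrD <- univariateCoxScreen(Xd, fx$time, fx$event)
  expect_true(scrD$degenerate[scrD$gene == "flat"])
  expect_true(is.na(scrD$wald_p[scrD$gene == "flat"]))

  expect_error(univariateCoxScreen(fx$X, fx$time, rep(0, 300)), "2 events")
})

test_that("ridge Cox limits: lambda -> 0 matches coxph, lambda -> Inf shrinks", {
  set.seed(72)
  n <- 40
  X <- cbind(gA = rnorm(n), gB = rnorm(n))
  time <- rexp(n, exp(0.6 * X[, 1]))
  event <- rbinom(n, 1, 0.8)
  ref <- survival::coxph(survival::Surv(time, event) ~ X, ties = "breslow")
  m0 <- fitRidgeCox(X, time, event, lambda = 1e-8)
  expect_equal(unname(modelCoef(m0)), unname(coef(ref)), tolerance = 1e-3)

  mInf <- fitRidgeCox(X, time, event, lambda = 1e6)
  expect_lt(max(abs(modelCoef(mInf))), 1e-4)
  # constant linear predictor at full shrinkage
  sv <- predictSurvival(mInf, X, c(1, 2))
  expect_lt(max(apply(sv, 2, sd)), 1e-3)

  # penalty monotonicity: larger lambda never increases the norm
  norms <- sapply(c(0.01, 0.1, 1, 10), function(l)
    sum(modelCoef(fitRidgeCox(X, time, event, lambda = l))^2))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("partial likelihood is invariant to time rescaling", {
  fx <- survCohort(seed = 73, n = 120, betas = c(g0001 = 0.8),
                   nGenes = 10)
  m1 <- fitRidgeCox(fx$X, fx$time, fx$event, lambda = 0.05)
  m2 <- fitRidgeCox(fx$X, fx$time * 365.25, fx$event, lambda = 0.05)
  expect_equal(modelCoef(m1), modelCoef(m2), tolerance = 1e-8)
})

test_that("Breslow baseline yields sane survival predictions", {
  fx <- survCohort(seed = 74, n = 200, betas = c(g0001 = 1), nGenes = 10)
  m <- fitRidgeCox(fx$X, fx$time, fx$event, nFolds = 5, seed = 1)
  grid <- c(0.5, 1, 2, 3)
  sv <- predictSurvival(m, fx$X, grid)
  expect_true(all(sv >= 0 & sv <= 1))
  expect_true(all(apply(sv, 1, diff) <= 1e-12))  # non-increasing in t
  # high-risk samples have lower predicted survival
  lp <- as.numeric(fx$X %*% modelCoef(m))
  expect_lt(cor(lp, sv[, 3]), -0.9)
})

test_that("Boot Lasso boundary and retained-set semantics", {
  fx <- survCohort(seed = 75, n = 150, betas = c(g0001 = 1.5),
                   nGenes = 20, censoring = 0.2)
  # B = 1: retention is that single lasso's support
  bl1 <- bootLassoCox(fx$X, fx$time, fx$event, B = 1, seed = 3,
                      cvFolds = 5)
  expect_setequal(retainedSet(bl1),
                  names(bl1@selectionCount)[bl1@selectionCount == 1])

  bl <- bootLassoCox(fx$X, fx$time, fx$event, B = 20, seed = 4,
                     cvFolds = 5)
  expect_true("g0001" %in% retainedSet(bl))
  expect_false(bl@emptySet)
  expect_s4_class(bl@finalModel, "CoxSignatureModel")
  expect_equal(bl@finalModel@penalty, "ridge")

  # retained set shrinks (weakly) as the retention threshold rises
  keep50 <- names(bl@selectionCount)[bl@selectionCount / 20 >= 0.5]
  keep80 <- names(bl@selectionCount)[bl@selectionCount / 20 >= 0.8]
  expect_true(all(keep80 %in% keep50))
})

test_that("Brier score matches the brute-force IPCW oracle", {
  fx <- toySurv()
  set.seed(76)
  S <- runif(8)
  for (t in c(0.7, 1.4, 2.2, 3.6)) {
    expect_equal(brierScore(fx$time, fx$event, S, t),
                 brierOracle(fx$time, fx$event, S, t), tolerance = 1e-10)
  }

  # no censoring, S = 0.5 everywhere -> BS(t) = 0.25 at every t
  tNC <- c(1, 2, 3, 4, 5)
  eNC <- rep(1, 5)
  for (t in c(0.5, 2.5, 4.5))
    expect_equal(brierScore(tNC, eNC, rep(0.5, 5), t), 0.25)

  # perfect oracle predictions, no censoring -> BS = 0
  tmid <- 2.5
  Sperf <- ifelse(tNC > tmid, 1, 0)
  expect_equal(brierScore(tNC, eNC, Sperf, tmid), 0)

  expect_error(brierScore(tNC, eNC, rep(1.5, 5), 1), "\\[0, 1\\]")
})

test_that("integrated Brier score: constant curve, duplication invariance", {
  fx <- toySurv()
  grid <- c(0, sort(unique(fx$time[fx$time <= 3])), 3)
  svC <- matrix(0.5, 8, length(grid))
  pec <- integratedBrier(fx$time, fx$event, svC, grid, tMax = 3,
                         modelLabel = "null")
  # constant BS(t) = c integrates to c
  expect_equal(ibs(pec), pec@brier[1], tolerance = 1e-12)

  # duplicating the whole test set leaves BS and IBS unchanged
  pec2 <- integratedBrier(rep(fx$time, 2), rep(fx$event, 2),
                          svC[rep(1:8, 2), ], grid, tMax = 3)
  expect_equal(pec2@brier, pec@brier, tolerance = 1e-12)
  expect_equal(ibs(pec2), ibs(pec), tolerance = 1e-12)

  # pointwise values agree with the scalar brierScore op
  set.seed(77)
  sv <- matrix(runif(8 * length(grid)), 8)
  pec3 <- integratedBrier(fx$time, fx$event, sv, grid, tMax = 3)
  expect_equal(pec3@brier[3],
               brierScore(fx$time, fx$event, sv[, 3], grid[3]),
               tolerance = 1e-12)
})

test_that("KM on uncensored data equals the empirical survival function", {
  time <- c(1, 2, 2, 3, 5, 8)
  event <- rep(1, 6)
  m <- fitNullSurvival(time, event)
  sv <- predictSurvival(m, matrix(0, 6, 1), c(1, 2, 3, 5, 8))
  ecdfS <- sapply(c(1, 2, 3, 5, 8), function(t) mean(time > t))
  expect_equal(unname(sv[1, ]), ecdfS, tolerance = 1e-9)
})

test_that("cross-validated IBS separates signal from null model", {
  fx <- survCohort(seed = 78, n = 200,
                   betas = c(g0001 = 1.2, g0002 = 0.9, g0003 = -0.9),
                   nGenes = 12, censoring = 0.3)
  curves <- cvPredictionError(fx$X, fx$time, fx$event,
                              models = c("null", "full_signature"),
                              nFolds = 5, seed = 2, cvFolds = 5)
  expect_lt(ibs(curves$full_signature), ibs(curves$null))
  expect_true(all(curves$null@brier >= 0 & curves$null@brier <= 1))

  # leave-one-out runs and returns a finite IBS on a small fixture
  fx2 <- survCohort(seed = 79, n = 30, betas = c(g0001 = 1), nGenes = 6,
                    censoring = 0.2)
  loo <- cvPredictionError(fx2$X, fx2$time, fx2$event, models = "null",
                           nFolds = 30, seed = 1)
  expect_true(is.finite(ibs(loo$null)))
})

test_that("conditional KM: span 1 equals the global KM; hand-worked n = 4", {
  fx <- survCohort(seed = 80, n = 40, betas = c(g0001 = 1), nGenes = 6,
                   censoring = 0.2)
  lp <- fx$X[, "g0001"]
  ck <- conditionalKM(lp, fx$time, fx$event, span = 1)
  km <- survival::survfit(survival::Surv(fx$time, fx$event) ~ 1)
  for (g in c("low", "medium", "high")) {
    expect_equal(ck[[g]]$time, km$time[km$n.event > 0])
    expect_equal(ck[[g]]$surv, km$surv[km$n.event > 0], tolerance = 1e-12)
  }

  # n = 4, span = 0.5: neighborhoods {v1,v2}, {v2,v3}, {v3,v4}
  v <- c(1, 2, 3, 4)
  tm <- c(2, 5, 1, 6); ev <- c(1, 1, 1, 0)
  ck2 <- conditionalKM(v, tm, ev, span = 0.5)
  # low neighborhood = samples 1,2: events at 2 and 5 -> S = 0.5, 0
  expect_equal(ck2$low$surv, c(0.5, 0))
  # high neighborhood = samples 3,4: event at 1, censored at 6 -> S = 0.5
  expect_equal(ck2$high$surv, 0.5)
  # medium anchored at median 2.5 -> samples 2,3 (ties by order)
  expect_equal(ck2$medium$surv, c(0.5, 0))

  expect_error(conditionalKM(v, tm, ev, span = 0.1), "at least 2")
})

test_that("strong signature separates conditional KM extremes", {
  wins <- 0
  for (s in 1:5) {
    fx <- survCohort(seed = 200 + s, n = 200, betas = c(g0001 = 1.5),
                     nGenes = 8, censoring = 0.25)
    m <- fitRidgeCox(fx$X, fx$time, fx$event, lambda = 0.05)
    lp <- as.numeric(fx$X %*% modelCoef(m))
    ck <- conditionalKM(lp, fx$time, fx$event, span = 0.25)
    s3 <- function(df) { i <- which(df$time <= 3); if (!length(i)) 1 else df$surv[max(i)] }
    if (s3(ck$low) > s3(ck$high)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("maxstat cut point: contracts and single-cut reduction", {
  set.seed(81)
  v <- 1:20
  tm <- rexp(20); ev <- rep(1, 20)
  expect_error(maxstatCutpoint(rep(1, 20), tm, ev), "identical")
  expect_error(maxstatCutpoint(v[1:8], tm[1:8], ev[1:8]), "10 samples")
  expect_error(maxstatCutpoint(v, tm, rep(0, 20)), "5 events")

  # degenerate epsilon -> single candidate -> pointwise p
  res <- maxstatCutpoint(v, tm, ev, epsilon = c(0.5, 0.5))
  expect_equal(res@adjustedP, 2 * pnorm(-res@maxStatistic),
               tolerance = 1e-12)

  # adjusted p is never below the pointwise p
  res2 <- maxstatCutpoint(v, tm, ev, epsilon = c(0.1, 0.9))
  expect_gte(res2@adjustedP, 2 * pnorm(-res2@maxStatistic) - 1e-12)
  expect_true(res2@cutQuantile >= 0.1 && res2@cutQuantile <= 0.9)
})

test_that("maxstat agrees with survdiff at a fixed cut", {
  set.seed(82)
  n <- 60
  v <- runif(n)
  tm <- rexp(n, 0.2 * ifelse(v > 0.5, 3, 1))
  ev <- rbinom(n, 1, 0.85)
  res <- maxstatCutpoint(v, tm, ev, epsilon = c(0.5, 0.5))
  # group at the same candidate cut the single-cut search used: the
  # single-candidate standardized statistic squared is the log-rank
  # chi-square (survdiff uses the identical variance formula)
  grp <- v > res@cutValue
  sd <- survival::survdiff(survival::Surv(tm, ev) ~ grp)
  expect_equal(res@maxStatistic^2, unname(sd$chisq), tolerance = 1e-8)
})
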