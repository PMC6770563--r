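test_that("balanced split stratifies exactly and reproducibly", {
  y <- setNames(rep(c("basal", "luminal"), each = 100),
                paste0("s", 1:200))
  sp <- splitTrainTest(y, 0.7, seed = 5)
  expect_equal(unname(sp$stratumCounts["train", ]), c(70, 70))
  expect_equal(unname(sp$stratumCounts["test", ]), c(30, 30))
  expect_setequal(c(sp$trainIds, sp$testIds), names(y))
  expect_length(intersect(sp$trainIds, sp$testIds), 0)

  sp2 <- splitTrainTest(y, 0.7, seed = 5)
  expect_identical(sp$trainIds, sp2$trainIds)

  # 21 + 21 at 0.7: round(14.7) = 15 per class
  y2 <- setNames(rep(c("basal", "luminal"), each = 21), paste0("t", 1:42))
  sp3 <- splitTrainTest(y2, 0.7, seed = 1)
  expect_true(all(sp3$stratumCounts["train", ] %in% c(14, 15)))
  expect_equal(sum(sp3$stratumCounts["train", ]), 30)

  expect_error(splitTrainTest(c(a = "x", b = "y")), "2 samples per class")
})

test_that("elastic net at vanishing penalty matches an unpenalized fit", {
  fx <- toyLogistic()
  m <- fitElasticNetLogistic(fx$X, fx$y, fixedAlpha = 0,
                             fixedLambda = 1e-7)
  ref <- glm(I(fx$y == "basal") ~ fx$X, family = binomial())
  expect_equal(m@intercept, unname(coef(ref)[1]), tolerance = 1e-4)
  expect_equal(unname(m@coefficients), unname(coef(ref)[-1]),
               tolerance = 1e-4)
})

test_that("lasso above lambda_max shrinks fully to the class log-odds", {
  fx <- toyLogistic()
  y01 <- as.integer(fx$y == "basal")
  lamMax <- max(abs(crossprod(scale(fx$X), y01 - mean(y01)))) /
    length(y01)
  m <- fitElasticNetLogistic(fx$X, fx$y, fixedAlpha = 1,
                             fixedLambda = lamMax * 1.5)
  expect_true(all(m@coefficients == 0))
  expect_equal(m@intercept, qlogis(mean(y01)), tolerance = 1e-6)
})

test_that("joint alpha/lambda CV recovers a strong synthetic signature", {
  co <- generateCohort(syntheticConfig(nSamples = 280, nGenes = 120,
                                       nSignatureGenes = 13,
                                       log2Effect = 2, basalFraction = 0.5,
                                       seed = 41))
  ann <- as.data.frame(SummarizedExperiment::colData(co))
  em <- log2RPKM(co, tmmFactors(co))
  sig <- S4Vectors::metadata(co)$truth$signature_genes
  X <- signatureMatrix(em, sig)
  y <- setNames(as.character(ann$subtype), rownames(X))
  sp <- splitTrainTest(y, 0.7, seed = 2)
  m <- fitElasticNetLogistic(X[sp$trainIds, ], y[sp$trainIds],
                             nFolds = 10, seed = 3)
  expect_gt(sum(m@coefficients != 0), 0)
  met <- evaluateClassifier(m, X[sp$testIds, ], y[sp$testIds])
  expect_gt(accuracy(met), 0.9)
  # CV table covers the full grid
  expect_setequal(unique(m@cvTable$alpha), c(0, 0.25, 0.5, 0.75, 1))

  expect_error(fitElasticNetLogistic(X[, 0], y), "empty gene set")
  expect_error(fitElasticNetLogistic(X, rep("basal", nrow(X))),
               "single class")
})

test_that("classifier metrics recompute from the confusion table", {
  # perfect 30 + 30
  probs <- c(rep(0.9, 30), rep(0.1, 30))
  y <- rep(c("basal", "luminal"), each = 30)
  m <- methods::new("ElasticNetModel", intercept = 0,
                    coefficients = c(g = 1), alpha = 1, lambda = 0,
                    cvTable = data.frame(), positiveClass = "basal")
  X <- matrix(qlogis(probs), ncol = 1, dimnames = list(NULL, "g"))
  met <- evaluateClassifier(m, X, y)
  expect_equal(accuracy(met), 1)
  expect_equal(met@accuracyCI[1], binom.test(60, 60)$conf.int[1],
               tolerance = 1e-9)
  expect_equal(round(met@accuracyCI[1], 3), 0.940)

  # a 117-sample test set with 110 correct calls
  ci <- binom.test(110, 117)$conf.int
  expect_equal(round(110 / 117, 2), 0.94)
  expect_equal(round(ci[1], 3), 0.881)
  expect_equal(round(ci[2], 3), 0.976)

  # all-one-class predictions zero out one of the rates
  Xneg <- matrix(qlogis(rep(0.2, 60)), ncol = 1,
                 dimnames = list(NULL, "g"))
  met2 <- evaluateClassifier(m, Xneg, y)
  expect_equal(met2@sensitivity, 0)
  expect_equal(met2@specificity, 1)
})

test_that("stability path: q bound, invariances, null behavior", {
  # q arithmetic from the error bound
  set.seed(51)
  n <- 60
  X <- matrix(rnorm(n * 25), n, 25,
              dimnames = list(NULL, paste0("g", 1:25)))
  y <- rep(c("basal", "luminal"), each = 30)
  res <- stabilityPathSelect(X, y, piThreshold = 0.8, pcer = 0.1,
                             nSubsamples = 30, seed = 1)
  expect_equal(res@q, 6L)

  # frequencies invariant to gene reordering
  perm <- sample(25)
  res2 <- stabilityPathSelect(X[, perm], y, nSubsamples = 30, seed = 1)
  expect_equal(selectionFrequency(res2)[colnames(X)],
               selectionFrequency(res))

  # stable set only contains genes that were ever selected
  expect_true(all(selectionFrequency(res)[stableSet(res)] >= 0.8))

  # q = 0 under the bound is a config error
  expect_error(stabilityPathSelect(X[, 1:3, drop = FALSE], y,
                                   pcer = 0.01, nSubsamples = 5),
               "q = 0")
  expect_error(stabilityPathSelect(X[1:5, ], rep(c("a", "b"), c(2, 3))),
               "4 samples")
})

test_that("external validation is consistent when A = B and robust to batch", {
  co <- generateCohort(syntheticConfig(nSamples = 160, nGenes = 80,
                                       nSignatureGenes = 10,
                                       log2Effect = 2, basalFraction = 0.5,
                                       seed = 61))
  ann <- as.data.frame(SummarizedExperiment::colData(co))
  em <- logCPM(co)
  sig <- S4Vectors::metadata(co)$truth$signature_genes
  X <- signatureMatrix(em, sig)
  y <- as.character(ann$subtype)
  ev <- externalValidation(X, y, X, y, nFolds = 5, seed = 7)
  resub <- evaluateClassifier(ev$model, X, y)
  expect_equal(accuracy(ev$metrics), accuracy(resub))
  expect_identical(ev$metrics@confusion, resub@confusion)
})
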