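test_that("duplicate averaging follows the mean + half-to-even rule", {
  cnt <- cbind(a1 = c(10, 3), a2 = c(20, 4), b = c(7, 9))
  rownames(cnt) <- c("g1", "g2")
  caseOf <- c(a1 = "A", a2 = "A", b = "B")
  out <- averageDuplicates(cnt, caseOf)
  expect_equal(colnames(out), c("A", "B"))
  expect_equal(out["g1", "A"], 15)   # mean(10, 20)
  expect_equal(out["g2", "A"], 4)    # 3.5 rounds half-to-even to 4
  expect_equal(out[, "B"], c(g1 = 7, g2 = 9))

  # no duplicates: identity; and the operation is idempotent
  single <- averageDuplicates(cnt, c(a1 = "x", a2 = "y", b = "z"))
  expect_equal(unname(single), unname(cnt))
  again <- averageDuplicates(out, setNames(colnames(out), colnames(out)))
  expect_equal(again, out)

  expect_error(averageDuplicates(cnt, c(a1 = "A", a2 = "A")), "not mapped")
})

test_that("TMM factors match the brute-force oracle and trivial fixtures", {
  # identical samples -> factors exactly 1
  same <- cbind(a = c(10, 20, 30, 40, 50), b = c(10, 20, 30, 40, 50))
  rownames(same) <- paste0("g", 1:5)
  expect_equal(unname(normFactors(tmmFactors(same))), c(1, 1))

  # pure depth change (second sample doubled) -> factors 1 after rescaling
  dbl <- cbind(a = c(10, 20, 30, 40, 50), b = 2 * c(10, 20, 30, 40, 50))
  rownames(dbl) <- paste0("g", 1:5)
  expect_equal(unname(normFactors(tmmFactors(dbl))), c(1, 1))

  # composition change: one high-count DE gene in sample 2
  cnt <- toyCounts()
  expect_equal(unname(normFactors(tmmFactors(cnt))),
               unname(tmmOracle(cnt)), tolerance = 1e-10)

  # random fixture, 4 samples
  set.seed(31)
  cnt2 <- matrix(rnbinom(200 * 4, mu = 60, size = 2), 200, 4,
                 dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  expect_equal(unname(normFactors(tmmFactors(cnt2))),
               unname(tmmOracle(cnt2)), tolerance = 1e-10)

  # geometric mean one
  expect_lt(abs(sum(log(normFactors(tmmFactors(cnt2))))), 1e-9)
})

test_that("TMM is invariant to gene order and global scaling", {
  set.seed(32)
  cnt <- matrix(rnbinom(150 * 3, mu = 40, size = 1), 150, 3,
                dimnames = list(paste0("g", 1:150), paste0("s", 1:3)))
  f1 <- normFactors(tmmFactors(cnt))
  f2 <- normFactors(tmmFactors(cnt[sample(nrow(cnt)), ]))
  expect_equal(f1, f2)
  f3 <- normFactors(tmmFactors(cnt * 3))
  expect_equal(f1, f3, tolerance = 1e-12)
})

test_that("TMM error cases are reported with the sample name", {
  expect_error(tmmFactors(matrix(1:5, ncol = 1)), "two samples")
  disjoint <- cbind(a = c(5, 5, 0, 0), b = c(4, 6, 0, 0),
                    z = c(0, 0, 7, 3))
  rownames(disjoint) <- paste0("g", 1:4)
  expect_error(tmmFactors(disjoint), "z")
})

test_that("log2-RPKM arithmetic, monotonicity and scaling invariance", {
  # count 0, pseudocount 0.5, libsize 1e6, factor 1, length 1000 -> -1
  cnt <- matrix(c(0, 1e6 - 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  em <- log2RPKM(cnt, geneLengths = c(1000, 1000), pseudocount = 0.5)
  expect_equal(exprValues(em)["g1", 1], -1)

  # count 100, libsize 1e6, length 2000, pseudocount 0 -> log2(50)
  cnt2 <- matrix(c(100, 1e6 - 100), 2, 1,
                 dimnames = list(c("g1", "g2"), "s1"))
  em2 <- log2RPKM(cnt2, geneLengths = c(2000, 1000), pseudocount = 0)
  expect_equal(exprValues(em2)["g1", 1], log2(50))

  # scaling a sample's counts (and hence libsize) by c is a no-op at pc 0
  set.seed(33)
  cnt3 <- matrix(rpois(40, 50) + 1, 20, 2,
                 dimnames = list(paste0("g", 1:20), c("s1", "s2")))
  lens <- sample(500:2000, 20)
  a <- exprValues(log2RPKM(cnt3, geneLengths = lens, pseudocount = 0))
  cnt3b <- cnt3; cnt3b[, 2] <- cnt3b[, 2] * 7
  b <- exprValues(log2RPKM(cnt3b, geneLengths = lens, pseudocount = 0))
  expect_equal(a[, 2], b[, 2])

  # strictly increasing in count
  expect_true(all(diff(exprValues(log2RPKM(
    matrix(c(1, 5, 9), 3, 1, dimnames = list(paste0("g", 1:3), "s")),
    geneLengths = rep(1000, 3)))[, 1]) > 0))
})

test_that("log-CPM matches its closed form and is monotone", {
  cnt <- matrix(c(500, 1e6 - 500), 2, 1,
                dimnames = list(c("g1", "g2"), "s1"))
  em <- logCPM(cnt, prior = 0.5)
  expect_equal(exprValues(em)["g1", 1], log2(500.5 / 1000001 * 1e6),
               tolerance = 1e-12)

  # prior 0 and count = libsize * 1e-6 gives exactly 0
  cnt2 <- matrix(c(1, 1e6 - 1), 2, 1, dimnames = list(c("g1", "g2"), "s"))
  expect_equal(exprValues(logCPM(cnt2, prior = 0))["g1", 1], 0)

  expect_error(logCPM(cnt, prior = -1), "prior")
  vals <- exprValues(logCPM(matrix(c(1, 10, 100), 3, 1,
                                   dimnames = list(paste0("g", 1:3), "s"))))
  expect_true(all(diff(vals[, 1]) > 0))
})

test_that("expression TSV round-trips with transform metadata", {
  co <- generateCohort(syntheticConfig(nSamples = 8, nGenes = 15, seed = 2))
  em <- log2RPKM(co, tmmFactors(co))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(em, path)
  back <- readExpressionMatrix(path)
  expect_equal(exprTransform(back), "log2_rpkm")
  expect_equal(back@pseudocount, 0.5)
  expect_equal(exprValues(back), exprValues(em), tolerance = 1e-9)
})

test_that("FFPE metadata filter drops flagged samples", {
  co <- generateCohort(syntheticConfig(nSamples = 10, nGenes = 12,
                                       nSignatureGenes = 3, seed = 4))
  SummarizedExperiment::colData(co)$ffpe <-
    rep(c(TRUE, FALSE), each = 5)
  expect_equal(ncol(dropFFPE(co)), 5)
})
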