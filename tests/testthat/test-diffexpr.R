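test_that("voom weights are positive and flat trends give flat weights", {
  # near-constant mean structure: Poisson-like counts at a common level
  set.seed(91)
  cnt <- matrix(rnbinom(400 * 12, mu = 200, size = 50), 400, 12,
                dimnames = list(paste0("g", 1:400), paste0("s", 1:12)))
  grp <- rep(c("A", "B"), each = 6)
  vw <- voomWeights(cnt, grp)
  expect_true(all(vw$weights > 0))
  expect_lt(sd(vw$weights) / mean(vw$weights), 0.2)
  expect_equal(exprTransform(vw$expr), "log_cpm")

  # doubling all library sizes leaves weights nearly invariant
  vw2 <- voomWeights(cnt * 2, grp)
  rel <- abs(vw2$weights / vw$weights - 1)
  expect_lt(median(rel), 0.05)

  expect_error(voomWeights(cnt, c("A", rep("B", 11))), "2 samples")
})

test_that("moderated t: forced-d0 limits bracket the ordinary t and z", {
  set.seed(92)
  G <- 300; n <- 10
  grp <- rep(0:1, each = 5)
  sdg <- sqrt(1 / rgamma(G, shape = 3, rate = 3))
  y <- matrix(rnorm(G * n), G, n) * sdg
  y[1:20, grp == 1] <- y[1:20, grp == 1] + 1.5
  rownames(y) <- paste0("g", 1:G)
  des <- model.matrix(~grp)

  # d0 = 0: ordinary per-gene pooled-variance t
  r0 <- moderatedTTest(y, des, priorDf = 0)
  tOrd <- apply(y, 1, function(r)
    t.test(r[grp == 1], r[grp == 0], var.equal = TRUE)$statistic)
  expect_equal(unname(r0$table$t), unname(tOrd), tolerance = 1e-10)

  # d0 = Inf: z statistic using the common prior variance s0^2, so
  # t_inf = t_0 * sqrt(s2_g / s0^2) gene by gene
  rInf <- moderatedTTest(y, des, priorDf = Inf)
  s2g <- apply(y, 1, function(r)
    (sum((r[grp == 0] - mean(r[grp == 0]))^2) +
       sum((r[grp == 1] - mean(r[grp == 1]))^2)) / (n - 2))
  expect_equal(unname(rInf$table$t),
               unname(r0$table$t * sqrt(s2g / rInf$priorVar)),
               tolerance = 1e-8)
  expect_true(all(is.infinite(rInf$table$df_total)))

  # estimated d0 interpolates between the two
  rHat <- moderatedTTest(y, des)
  expect_true(is.finite(rHat$priorDf) && rHat$priorDf > 0)
  expect_true(all(rHat$table$fdr >= rHat$table$p_value - 1e-12))
})

test_that("moderated t matches limma::eBayes on heteroscedastic data", {
  set.seed(93)
  G <- 400; n <- 10
  grp <- rep(0:1, each = 5)
  sdg <- sqrt(1 / rgamma(G, shape = 2, rate = 2))
  y <- matrix(rnorm(G * n), G, n) * sdg
  rownames(y) <- paste0("g", 1:G)
  des <- model.matrix(~grp)
  mine <- moderatedTTest(y, des)
  ref <- limma::eBayes(limma::lmFit(y, des))
  expect_equal(mine$priorDf, ref$df.prior, tolerance = 1e-6)
  expect_equal(mine$priorVar, ref$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mine$table$t), unname(ref$t[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment is a monotone step-up on sorted p-values", {
  set.seed(94)
  y <- matrix(rnorm(100 * 8), 100, 8)
  rownames(y) <- paste0("g", 1:100)
  res <- moderatedTTest(y, rep(0:1, each = 4))
  tab <- res$table[order(res$table$p_value), ]
  expect_true(all(diff(tab$fdr) >= -1e-12))
  expect_equal(tab$fdr, p.adjust(tab$p_value, "BH"))
})

test_that("ddCT quantification follows the comparative-CT definitions", {
  mk <- function(cond, gene, dct, nrep = 3, ref = 20) {
    data.frame(sample = paste0(cond, gene, seq_len(nrep)),
               condition = cond, gene = gene,
               ct_target = ref + dct, ct_ref = ref)
  }
  rec <- rbind(
    mk("ctrl", "FOS", c(5.0, 5.1, 4.9)),
    mk("trt", "FOS", c(5.0, 5.1, 4.9) + 0.81),   # ddCT 0.81 -> FC 0.57
    mk("ctrl", "MYC", c(3.0, 3.2, 2.8)),
    mk("trt", "MYC", c(2.0, 2.2, 1.8)))          # ddCT -1 -> FC 2
  out <- ddctQuantify(rec, controlCondition = "ctrl")

  fosT <- out[out$gene == "FOS" & out$condition == "trt", ]
  expect_equal(fosT$ddct, 0.81, tolerance = 1e-9)
  expect_equal(fosT$fc, 2^-0.81, tolerance = 1e-9)
  expect_equal(round(fosT$fc, 2), 0.57)

  mycT <- out[out$gene == "MYC" & out$condition == "trt", ]
  expect_equal(mycT$ddct, -1, tolerance = 1e-9)
  expect_equal(mycT$fc, 2, tolerance = 1e-9)

  # control rows: ddCT 0, FC 1
  ctl <- out[out$condition == "ctrl", ]
  expect_true(all(abs(ctl$ddct) < 1e-12))
  expect_true(all(abs(ctl$fc - 1) < 1e-12))

  # swapping condition and control inverts the fold change
  out2 <- ddctQuantify(rec, controlCondition = "trt")
  fosC <- out2[out2$gene == "FOS" & out2$condition == "ctrl", ]
  expect_equal(fosC$fc, 1 / fosT$fc, tolerance = 1e-9)

  # t-test on replicate dCT values matches a direct Student t
  tRef <- t.test(c(5.0, 5.1, 4.9) + 0.81, c(5.0, 5.1, 4.9),
                 var.equal = TRUE)$p.value
  expect_equal(fosT$t_p, tRef, tolerance = 1e-12)
})

test_that("ddCT input validation: missing reference and CT range", {
  rec <- data.frame(sample = c("a", "b", "c", "d"),
                    condition = c("ctrl", "ctrl", "trt", "trt"),
                    gene = "FOS", ct_target = c(21, 22, 23, 24),
                    ct_ref = c(20, NA, 20, 20))
  expect_message(
    expect_error(ddctQuantify(rec, "ctrl"), "2 control replicates"),
    "rejected")
  bad <- rec; bad$ct_ref <- c(20, 20, 20, 50)
  expect_error(ddctQuantify(bad, "ctrl"), "\\(0, 45\\)")
})

test_that("duplicate wells are averaged before dCT", {
  rec <- data.frame(
    sample = c("s1", "s1", "s2", "s3", "s4"),
    condition = c("ctrl", "ctrl", "ctrl", "trt", "trt"),
    gene = "FOS",
    ct_target = c(24.0, 26.0, 25.2, 26.0, 26.2),
    ct_ref = c(20, 20, 20, 20, 20))
  out <- ddctQuantify(rec, "ctrl")
  trt <- out[out$condition == "trt", ]
  # s1 wells average to 25 -> control dCT (5, 5.2), treated (6, 6.2)
  expect_equal(trt$ddct, 1, tolerance = 1e-12)
  expect_equal(trt$fc, 0.5, tolerance = 1e-12)
})
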