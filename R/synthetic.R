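#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the stated generative model: negative-binomial
#' counts with a basal-vs-luminal differential signature, optional batch
#' structure on the log2-mean scale, and Weibull overall-survival times whose
#' log hazard is linear in standardized signature expression, with
#' independent exponential censoring calibrated to a target fraction.
#'
#' Defaults describe a TCGA-like bladder cohort: 388 de-duplicated samples,
#' a 13-gene basal signature with a 2 log2-fold-change separation, moderate
#' NB dispersion, and 50 percent censoring (the source cohorts do not report
#' their censoring fraction; this is a placeholder, not an estimate).
#'
#' @param nSamples,nGenes Cohort dimensions.
#' @param nSignatureGenes Number of genes carrying the subtype effect
#'   (0 gives a null cohort).
#' @param basalFraction Proportion of basal samples; the basal count is
#'   `round(basalFraction * nSamples)`.
#' @param log2Effect Per-signature-gene basal-vs-luminal log2 fold change.
#' @param nbDispersion NB dispersion phi (var = mu + phi mu^2).
#' @param libsizeRange Range of relative library-size factors (uniform).
#' @param geneLengthRange Range of gene lengths in bp (uniform integers).
#' @param nBatches Number of batches; batch 1 is the reference.
#' @param batchShift Additive log2-mean shift applied to affected genes in
#'   batches 2..nBatches.
#' @param batchScale Variance multiplier for affected genes in non-reference
#'   batches, realized as per-observation lognormal noise on the NB mean
#'   with log2-variance `log2(batchScale)` (none when 1).
#' @param batchAffectedFraction Fraction of genes receiving the batch effect.
#' @param coxBetas Named numeric vector of true log-hazard coefficients on
#'   per-gene standardized log2 expression (names are gene ids such as
#'   `"g0001"`); NULL or empty for no survival signal.
#' @param weibullShape Weibull shape k of the event-time distribution.
#' @param baselineRate Baseline rate lambda0 (per year).
#' @param targetCensoring Desired censoring fraction in \[0, 1\]; the
#'   exponential censoring rate is calibrated by bisection on the drawn
#'   event times.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated list of class `"SyntheticConfig"`.
#' @seealso [generateCohort()]
#' @export
syntheticConfig <- function(nSamples = 388L, nGenes = 2000L,
                            nSignatureGenes = 13L, basalFraction = 0.4,
                            log2Effect = 2, nbDispersion = 0.2,
                            libsizeRange = c(0.5, 1.5),
                            geneLengthRange = c(500L, 10000L),
                            nBatches = 1L, batchShift = 0,
                            batchScale = 1, batchAffectedFraction = 0.5,
                            coxBetas = NULL, weibullShape = 1.2,
                            baselineRate = 0.1, targetCensoring = 0.5,
                            seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
              nSignatureGenes = as.integer(nSignatureGenes),
              basalFraction = basalFraction, log2Effect = log2Effect,
              nbDispersion = nbDispersion, libsizeRange = libsizeRange,
              geneLengthRange = geneLengthRange,
              nBatches = as.integer(nBatches), batchShift = batchShift,
              batchScale = batchScale,
              batchAffectedFraction = batchAffectedFraction,
              coxBetas = coxBetas, weibullShape = weibullShape,
              baselineRate = baselineRate,
              targetCensoring = targetCensoring, seed = as.integer(seed))
  with(cfg, {
    if (nSamples < 1 || nGenes < 1) stopf("nSamples and nGenes must be positive")
    if (nSignatureGenes < 0 || nSignatureGenes > nGenes)
      stopf("need 0 <= nSignatureGenes <= nGenes")
    if (basalFraction < 0 || basalFraction > 1)
      stopf("basalFraction must be in [0, 1]")
    if (nbDispersion <= 0) stopf("nbDispersion must be positive")
    if (diff(libsizeRange) < 0 || any(libsizeRange <= 0))
      stopf("libsizeRange must be ordered positive")
    if (diff(geneLengthRange) < 0 || any(geneLengthRange <= 0))
      stopf("geneLengthRange must be ordered positive")
    if (batchScale < 1) stopf("batchScale must be >= 1")
    if (weibullShape <= 0 || baselineRate <= 0)
      stopf("weibullShape and baselineRate must be positive")
    if (targetCensoring < 0 || targetCensoring >= 1)
      stopf("targetCensoring must be in [0, 1)")
  })
  structure(cfg, class = "SyntheticConfig")
}

# Exponential censoring rate hitting the target fraction, by bisection on
# the realized event times (deterministic given the times).
calibrateCensoringRate <- function(eventTimes, target, tol = 1e-6) {
  frac <- function(r) mean(1 - exp(-r * eventTimes))
  lo <- 1e-10; hi <- 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (frac(mid) < target) lo <- mid else hi <- mid
    if (hi / lo < 1 + tol) break
  }
  sqrt(lo * hi)
}

#' Generate a synthetic bladder-cancer cohort
#'
#' Draws counts `Y_gs ~ NB(mu_gs, phi)` with
#' `log2 mu_gs = baseline_g + Delta * 1(g in signature, s basal) +
#' batch_b(g, s) + log2(libfactor_s)`; baseline counts are
#' lognormal(meanlog 4, sdlog 1.5) to mimic RNA-seq dynamic range. Overall
#' survival is Weibull: `T = (-log U / (lambda0 exp(eta)))^(1/k)` with
#' `eta = sum_g beta_g z_gs` on per-gene standardized log2 expression of the
#' generated cohort itself, censored by an independent exponential time
#' whose rate is calibrated so the realized censoring fraction approximates
#' the target. Fully reproducible from the config seed.
#'
#' @param config A [syntheticConfig()] object.
#' @return A [UBCCohort-class] with `counts`, gene lengths, clinical
#'   annotation (`subtype`, `batch`, `os_time`, `os_event`) and
#'   `metadata(x)$truth` recording signature genes, true labels, true
#'   coefficients and batch parameters.
#' @examples
#' cohort <- generateCohort(syntheticConfig(nSamples = 40, nGenes = 100,
#'                                          nSignatureGenes = 5, seed = 7))
#' table(SummarizedExperiment::colData(cohort)$subtype)
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  withSeed(config$seed, {
    G <- config$nGenes; n <- config$nSamples
    geneIds <- sprintf("g%04d", seq_len(G))
    sampleIds <- sprintf("s%04d", seq_len(n))
    lengths <- sample(config$geneLengthRange[1]:config$geneLengthRange[2],
                      G, replace = TRUE)
    baseline <- log2(rlnorm(G, meanlog = 4, sdlog = 1.5))
    sigGenes <- geneIds[seq_len(config$nSignatureGenes)]

    nBasal <- round(config$basalFraction * n)
    subtype <- rep("luminal", n)
    subtype[sample.int(n, nBasal)] <- "basal"

    batch <- sample(rep_len(seq_len(config$nBatches), n))
    affected <- if (config$nBatches > 1)
      sort(sample.int(G, round(config$batchAffectedFraction * G)))
    else integer(0)

    log2mu <- matrix(baseline, G, n)
    if (length(sigGenes))
      log2mu[seq_along(sigGenes), subtype == "basal"] <-
        log2mu[seq_along(sigGenes), subtype == "basal"] + config$log2Effect
    if (length(affected)) {
      noiseSd <- sqrt(max(0, log2(config$batchScale)))
      for (b in 2:config$nBatches) {
        cols <- which(batch == b)
        log2mu[affected, cols] <- log2mu[affected, cols] + config$batchShift +
          if (noiseSd > 0)
            matrix(rnorm(length(affected) * length(cols), 0, noiseSd),
                   length(affected), length(cols))
          else 0
      }
    }
    libfactor <- runif(n, config$libsizeRange[1], config$libsizeRange[2])
    log2mu <- sweep(log2mu, 2, log2(libfactor), `+`)

    counts <- matrix(rnbinom(G * n, mu = 2^log2mu,
                             size = 1 / config$nbDispersion), G, n,
                     dimnames = list(geneIds, sampleIds))

    betas <- config$coxBetas
    eta <- rep(0, n)
    if (length(betas)) {
      missing <- setdiff(names(betas), geneIds)
      if (length(missing))
        stopf("coxBetas name genes absent from the cohort: %s",
              paste(missing, collapse = ", "))
      lx <- log2(counts[names(betas), , drop = FALSE] + 0.5)
      z <- (lx - rowMeans(lx)) /
        pmax(apply(lx, 1, sd), .Machine$double.eps)
      eta <- as.numeric(crossprod(z, betas))
    }
    u <- runif(n)
    eventTime <- (-log(u) / (config$baselineRate * exp(eta)))^
      (1 / config$weibullShape)
    if (config$targetCensoring > 0) {
      rate <- calibrateCensoringRate(eventTime, config$targetCensoring)
      censTime <- rexp(n, rate)
    } else censTime <- rep(Inf, n)
    osTime <- pmin(eventTime, censTime)
    osEvent <- as.integer(eventTime <= censTime)

    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      rowData = S4Vectors::DataFrame(length_bp = lengths,
                                     is_signature = geneIds %in% sigGenes,
                                     row.names = geneIds),
      colData = S4Vectors::DataFrame(
        subtype = factor(subtype, levels = c("luminal", "basal")),
        batch = factor(batch), os_time = osTime, os_event = osEvent,
        libfactor = libfactor, row.names = sampleIds),
      metadata = list(truth = list(
        signature_genes = sigGenes, subtype = setNames(subtype, sampleIds),
        cox_betas = betas, batch_shift = config$batchShift,
        batch_scale = config$batchScale,
        batch_affected_genes = geneIds[affected],
        event_time = eventTime, config = unclass(config))))
    methods::new("UBCCohort", se)
  })
}

# Subtype-conditional Beta means for the IHC marker panel (fractions of
# positive tumor cells). Basal cases are keratin-5/6 and -14 rich and
# pSTAT3/MYC/FOSL1 high; luminal cases express CK20 and uroplakin-2.
.ihcMarkerMeans <- rbind(
  basal    = c(CK5_6 = 0.70, CK14 = 0.50, CK20 = 0.05, UPK2 = 0.02,
               pSTAT3 = 0.60, MYC = 0.55, FOSL1 = 0.55),
  luminal  = c(CK5_6 = 0.05, CK14 = 0.05, CK20 = 0.60, UPK2 = 0.40,
               pSTAT3 = 0.15, MYC = 0.20, FOSL1 = 0.12),
  nontype  = c(CK5_6 = 0.30, CK14 = 0.25, CK20 = 0.30, UPK2 = 0.12,
               pSTAT3 = 0.35, MYC = 0.35, FOSL1 = 0.30))

#' Generate a synthetic immunohistochemistry cohort
#'
#' Per-case percent-positive tumor-cell values for the seven IHC markers
#' (CK5/6, CK14, CK20, UPK2, pSTAT3, MYC, FOSL1) drawn from
#' subtype-conditional Beta distributions with the means in
#' `markerMeans` (rows basal / luminal / nontype) and common precision
#' `precision` (Beta(m*nu, (1-m)*nu)).
#'
#' @param nCases Number of cases (0 gives an empty table).
#' @param subtypeProbs Named probabilities over
#'   `c("basal", "luminal", "nontype")`; must sum to 1.
#' @param seed Integer seed.
#' @param markerMeans Optional replacement for the default mean matrix.
#' @param precision Beta precision nu (default 20).
#' @return data.frame with `case_id`, `true_subtype` and one percent column
#'   per marker.
#' @export
generateIHCCohort <- function(nCases,
                              subtypeProbs = c(basal = 0.3, luminal = 0.5,
                                               nontype = 0.2),
                              seed = 1L, markerMeans = .ihcMarkerMeans,
                              precision = 20) {
  if (abs(sum(subtypeProbs) - 1) > 1e-8)
    stopf("subtypeProbs must sum to 1")
  markers <- colnames(markerMeans)
  if (nCases == 0) {
    out <- as.data.frame(setNames(
      c(list(character(0), character(0)),
        rep(list(numeric(0)), length(markers))),
      c("case_id", "true_subtype", markers)))
    return(out)
  }
  withSeed(seed, {
    classes <- names(subtypeProbs)[subtypeProbs > 0]
    truth <- sample(names(subtypeProbs), nCases, replace = TRUE,
                    prob = subtypeProbs)
    vals <- sapply(markers, function(m) {
      mu <- markerMeans[truth, m]
      100 * rbeta(nCases, mu * precision, (1 - mu) * precision)
    })
    vals <- matrix(vals, nrow = nCases,
                   dimnames = list(NULL, markers))
    data.frame(case_id = sprintf("case%04d", seq_len(nCases)),
               true_subtype = truth, vals, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
}

#' Write a cohort to plain-text files
#'
#' Writes `counts.tsv` (gene_id, length_bp, one column per sample),
#' `annotation.tsv` (sample_id, subtype, batch, os_time, os_event) and, for
#' synthetic cohorts, `truth.json`.
#'
#' @param cohort A [UBCCohort-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  countsPath <- file.path(dir, "counts.tsv")
  annPath <- file.path(dir, "annotation.tsv")
  cnt <- cohortCounts(cohort)
  df <- data.frame(gene_id = rownames(cnt),
                   length_bp = cohortLengths(cohort), cnt,
                   check.names = FALSE, row.names = NULL)
  write.table(df, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- cohortAnnotation(cohort)
  write.table(ann, annPath, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(countsPath, annPath)
  truth <- S4Vectors::metadata(cohort)$truth
  if (!is.null(truth)) {
    truthPath <- file.path(dir, "truth.json")
    keep <- truth[setdiff(names(truth), "event_time")]
    jsonlite::write_json(keep, truthPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, truthPath)
  }
  invisible(paths)
}
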