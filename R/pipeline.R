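#' Build a pipeline run configuration
#'
#' A validated, JSON-serializable description of an end-to-end run:
#' synthesize (or load) a cohort, normalize, batch-adjust, classify
#' subtypes from the signature, model overall survival, and write a
#' report. One global seed expands deterministically into per-stage seeds.
#'
#' @param outDir Output directory for all stage artifacts.
#' @param synthetic NULL, or a list of [syntheticConfig()] arguments used
#'   to generate the cohort.
#' @param countsFile,annotationFile Input TSVs when `synthetic` is NULL.
#' @param signatureGenes Gene ids used by the classifier and survival
#'   stages; NULL takes the synthetic truth signature.
#' @param stages Character subset of
#'   `c("normalize", "batch", "classify", "survival")`.
#' @param splitProportion Train fraction of the balanced split.
#' @param alphaGrid,nFolds Elastic-net tuning grid and CV folds.
#' @param stability list(pi, pcer, nSubsamples) for the stability path.
#' @param bootLasso NULL to skip, or list(B, retainFraction, cvFolds).
#' @param span Conditional-KM neighborhood fraction.
#' @param epsilon Cut-point quantile search range.
#' @param tMax Brier-score horizon in years.
#' @param seed Global integer seed.
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(outDir, synthetic = NULL, countsFile = NULL,
                      annotationFile = NULL, signatureGenes = NULL,
                      stages = c("normalize", "batch", "classify",
                                 "survival"),
                      splitProportion = 0.7,
                      alphaGrid = c(0, 0.25, 0.5, 0.75, 1), nFolds = 10L,
                      stability = list(pi = 0.8, pcer = 0.1,
                                       nSubsamples = 100L),
                      bootLasso = NULL, span = 0.25,
                      epsilon = c(0.1, 0.9), tMax = 3, seed = 1L) {
  stages <- match.arg(stages, c("normalize", "batch", "classify",
                                "survival"), several.ok = TRUE)
  cfg <- list(outDir = outDir, synthetic = synthetic,
              countsFile = countsFile, annotationFile = annotationFile,
              signatureGenes = signatureGenes, stages = stages,
              splitProportion = splitProportion, alphaGrid = alphaGrid,
              nFolds = as.integer(nFolds), stability = stability,
              bootLasso = bootLasso, span = span, epsilon = epsilon,
              tMax = tMax, seed = as.integer(seed))
  # upfront validation: every enabled stage must have resolvable inputs
  if (is.null(synthetic)) {
    if (is.null(countsFile) || !file.exists(countsFile))
      stopf("config error: counts file missing")
    if (any(c("classify", "survival") %in% stages) &&
        (is.null(annotationFile) || !file.exists(annotationFile)))
      stopf("config error: annotation file required for classify/survival")
    if (any(c("classify", "survival") %in% stages) &&
        is.null(signatureGenes))
      stopf("config error: signatureGenes required without synthetic truth")
  }
  structure(cfg, class = "RunConfig")
}

#' Bundled demo configuration
#'
#' A small fully synthetic end-to-end run (well under the 10-minute,
#' one-CPU envelope): two batches with a location/scale batch effect, a
#' 13-gene subtype signature, three prognostic genes, and all analysis
#' stages enabled.
#'
#' @param outDir Output directory.
#' @param seed Global seed.
#' @return A `"RunConfig"`.
#' @export
demoRunConfig <- function(outDir, seed = 1L) {
  runConfig(outDir,
            synthetic = list(nSamples = 160, nGenes = 300,
                             nSignatureGenes = 13, basalFraction = 0.4,
                             log2Effect = 2, nBatches = 2, batchShift = 1,
                             batchScale = 1.5,
                             coxBetas = c(g0001 = 0.8, g0002 = 0.5,
                                          g0003 = -0.5),
                             targetCensoring = 0.4),
            stability = list(pi = 0.8, pcer = 0.1, nSubsamples = 50L),
            bootLasso = list(B = 50L, retainFraction = 0.5, cvFolds = 5L),
            nFolds = 10L, seed = seed)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — synthesize/load,
#' normalize (TMM + log2-RPKM), batch-adjust, classify (balanced split,
#' joint alpha/lambda elastic net, stability path), survival (univariate
#' screen, cross-validated IBS for null/ridge(/Boot Lasso) models,
#' conditional KM, maximally selected cut point) — writing every
#' intermediate artifact under `config$outDir` and returning a run report.
#' Reruns with the same config reproduce all stochastic outputs exactly.
#'
#' @param config A [runConfig()] object.
#' @return list of class `"RunReport"`: per-stage parameter echo and
#'   metrics, package version, config hash, wall-clock seconds per stage.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- expandSeed(config$seed,
                      c("synthesize", "split", "classify", "stability",
                        "survival", "bootlasso"))
  cfgPath <- file.path(config$outDir, "config.json")
  jsonlite::write_json(unclass(config), cfgPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  # hash covers the analysis parameters, not the output location
  hashPath <- tempfile(fileext = ".json")
  hashCfg <- unclass(config); hashCfg$outDir <- NULL
  jsonlite::write_json(hashCfg, hashPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  report <- list(package_version = as.character(
                   utils::packageVersion("ubcsig")),
                 config_hash = unname(tools::md5sum(hashPath)),
                 seeds = as.list(seeds), stages = list(), timings = list())
  tic <- function() Sys.time()
  tocAdd <- function(stage, t0)
    report$timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")

  runStage <- function(stage, fn) {
    t0 <- tic()
    res <- tryCatch(fn(), error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
    tocAdd(stage, t0)
    res
  }

  # --- data ------------------------------------------------------------
  cohort <- runStage("data", function() {
    if (!is.null(config$synthetic)) {
      args <- config$synthetic
      args$seed <- seeds[["synthesize"]]
      co <- generateCohort(do.call(syntheticConfig, args))
      writeCohort(co, config$outDir)
      co
    } else {
      dropFFPE(readCountMatrix(config$countsFile, config$annotationFile))
    }
  })
  sigGenes <- config$signatureGenes %||%
    S4Vectors::metadata(cohort)$truth$signature_genes
  ann <- cohortAnnotation(cohort)

  # --- normalize -------------------------------------------------------
  expr <- NULL
  if ("normalize" %in% config$stages) {
    expr <- runStage("normalize", function() {
      tmm <- tmmFactors(cohort)
      em <- log2RPKM(cohort, tmm = tmm)
      writeExpressionMatrix(em, file.path(config$outDir, "expression.tsv"))
      jsonlite::write_json(as.list(normFactors(tmm)),
                           file.path(config$outDir, "tmm_factors.json"),
                           auto_unbox = TRUE, digits = NA)
      em
    })
  }

  # --- batch adjustment ------------------------------------------------
  if ("batch" %in% config$stages && !is.null(expr) &&
      "batch" %in% colnames(ann) && length(unique(ann$batch)) > 1) {
    expr <- runStage("batch", function() {
      res <- combatAdjust(expr, ann$batch)
      writeComBatParams(res$params,
                        file.path(config$outDir, "combat_params.json"))
      writeExpressionMatrix(res$adjusted,
                            file.path(config$outDir,
                                      "expression_adjusted.tsv"))
      res$adjusted
    })
    report$stages$batch <- list(adjusted = TRUE)
  }

  # --- classification --------------------------------------------------
  if ("classify" %in% config$stages) {
    stopifnot(!is.null(expr), "subtype" %in% colnames(ann))
    res <- runStage("classify", function() {
      keep <- ann$subtype %in% c("basal", "luminal")
      X <- signatureMatrix(expr, sigGenes)[keep, , drop = FALSE]
      y <- setNames(as.character(ann$subtype[keep]), ann$sample_id[keep])
      split <- splitTrainTest(y, config$splitProportion,
                              seed = seeds[["split"]])
      model <- fitElasticNetLogistic(X[split$trainIds, , drop = FALSE],
                                     y[split$trainIds],
                                     alphaGrid = config$alphaGrid,
                                     nFolds = config$nFolds,
                                     seed = seeds[["classify"]])
      metrics <- evaluateClassifier(model, X[split$testIds, , drop = FALSE],
                                    y[split$testIds])
      stab <- stabilityPathSelect(X[split$trainIds, , drop = FALSE],
                                  y[split$trainIds],
                                  piThreshold = config$stability$pi,
                                  pcer = config$stability$pcer,
                                  nSubsamples = config$stability$nSubsamples,
                                  seed = seeds[["stability"]])
      jsonlite::write_json(list(
        intercept = model@intercept,
        coefficients = as.list(model@coefficients),
        alpha = model@alpha, lambda = model@lambda),
        file.path(config$outDir, "classifier_model.json"),
        auto_unbox = TRUE, digits = NA)
      jsonlite::write_json(list(
        accuracy = accuracy(metrics),
        accuracy_ci = metrics@accuracyCI,
        sensitivity = metrics@sensitivity,
        specificity = metrics@specificity,
        confusion = as.data.frame(metrics@confusion),
        stable_set = stableSet(stab),
        selection_frequency = as.list(selectionFrequency(stab))),
        file.path(config$outDir, "classifier_metrics.json"),
        auto_unbox = TRUE, digits = NA)
      list(model = model, metrics = metrics, stability = stab,
           split = split)
    })
    report$stages$classify <- list(
      accuracy = accuracy(res$metrics),
      accuracy_ci = res$metrics@accuracyCI,
      sensitivity = res$metrics@sensitivity,
      specificity = res$metrics@specificity,
      alpha = res$model@alpha, lambda = res$model@lambda,
      stable_set = stableSet(res$stability))
  }

  # --- survival --------------------------------------------------------
  if ("survival" %in% config$stages) {
    stopifnot(!is.null(expr),
              all(c("os_time", "os_event") %in% colnames(ann)))
    res <- runStage("survival", function() {
      X <- signatureMatrix(expr, sigGenes)
      tm <- ann$os_time; ev <- ann$os_event
      screen <- univariateCoxScreen(X, tm, ev)
      models <- c("null", "full_signature",
                  if (!is.null(config$bootLasso)) "boot_lasso")
      blArgs <- config$bootLasso %||% list(B = 200L, retainFraction = 0.5,
                                           cvFolds = 10L)
      curves <- cvPredictionError(X, tm, ev, models = models,
                                  nFolds = config$nFolds,
                                  seed = seeds[["survival"]],
                                  tMax = config$tMax, B = blArgs$B,
                                  retainFraction = blArgs$retainFraction,
                                  cvFolds = blArgs$cvFolds)
      ridge <- fitRidgeCox(X, tm, ev, nFolds = config$nFolds,
                           seed = seeds[["survival"]])
      lp <- as.numeric(X %*% modelCoef(ridge))
      ckm <- conditionalKM(lp, tm, ev, span = config$span)
      cut <- maxstatCutpoint(lp, tm, ev, epsilon = config$epsilon)

      write.table(screen, file.path(config$outDir, "cox_screen.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      curveTab <- do.call(rbind, lapply(names(curves), function(m)
        data.frame(model = m, time = curves[[m]]@times,
                   brier = curves[[m]]@brier)))
      write.table(curveTab, file.path(config$outDir,
                                      "prediction_error_curves.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      kmTab <- do.call(rbind, lapply(names(ckm), function(g)
        cbind(group = g, ckm[[g]])))
      write.table(kmTab, file.path(config$outDir, "conditional_km.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(
        cut_value = cut@cutValue, cut_quantile = cutQuantile(cut),
        max_statistic = cut@maxStatistic, adjusted_p = cut@adjustedP),
        file.path(config$outDir, "cutpoint.json"), auto_unbox = TRUE,
        digits = NA)
      jsonlite::write_json(as.list(modelCoef(ridge)),
                           file.path(config$outDir, "cox_model.json"),
                           auto_unbox = TRUE, digits = NA)
      list(screen = screen, curves = curves, cut = cut)
    })
    report$stages$survival <- list(
      ibs = lapply(res$curves, ibs),
      cut_quantile = cutQuantile(res$cut),
      cut_adjusted_p = res$cut@adjustedP)
  }

  report$stages$data <- list(
    n_samples = ncol(cohort), n_genes = nrow(cohort),
    signature_genes = sigGenes)
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  structure(report, class = "RunReport")
}
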