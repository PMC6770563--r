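#' Read a count matrix (and optional clinical annotation) from TSV
#'
#' The counts file has columns `gene_id`, `length_bp`, then one integer
#' column per sample. The optional annotation file is keyed by `sample_id`
#' and may carry `subtype`, `batch`, `os_time`, `os_event`, `ffpe`, etc.
#'
#' @param countsFile Path to the counts TSV.
#' @param annotationFile Optional path to the clinical TSV.
#' @return A [UBCCohort-class].
#' @export
readCountMatrix <- function(countsFile, annotationFile = NULL) {
  df <- read.delim(countsFile, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% colnames(df)))
    stopf("counts TSV must have gene_id and length_bp columns")
  cnt <- as.matrix(df[, setdiff(colnames(df), c("gene_id", "length_bp")),
                      drop = FALSE])
  rownames(cnt) <- df$gene_id
  storage.mode(cnt) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(cnt))
  if (!is.null(annotationFile)) {
    ann <- read.delim(annotationFile, stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(ann))
      stopf("annotation TSV must have a sample_id column")
    missing <- setdiff(colnames(cnt), ann$sample_id)
    if (length(missing))
      stopf("samples missing from annotation: %s",
            paste(missing, collapse = ", "))
    ann <- ann[match(colnames(cnt), ann$sample_id), , drop = FALSE]
    cd <- S4Vectors::DataFrame(ann[setdiff(colnames(ann), "sample_id")],
                               row.names = colnames(cnt))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt),
    rowData = S4Vectors::DataFrame(length_bp = df$length_bp,
                                   row.names = df$gene_id),
    colData = cd)
  methods::new("UBCCohort", se)
}

#' Drop samples flagged as FFPE
#'
#' Formalin-fixed samples are excluded by metadata before any analysis; no
#' assay-based detection is attempted.
#'
#' @param cohort A [UBCCohort-class] whose colData has a logical `ffpe`
#'   column (absent column means nothing is dropped).
#' @return The filtered cohort.
#' @export
dropFFPE <- function(cohort) {
  cd <- SummarizedExperiment::colData(cohort)
  if (!"ffpe" %in% colnames(cd)) return(cohort)
  cohort[, !as.logical(cd$ffpe)]
}

#' Average technical duplicate samples into one column per case
#'
#' Duplicated cases are replaced by the arithmetic mean of their columns,
#' rounded half-to-even back to integers so count semantics are preserved;
#' singleton cases pass through unchanged. Idempotent once every case is a
#' singleton.
#'
#' @param x Count matrix (genes x samples) or [UBCCohort-class].
#' @param caseOf Named map sample id -> case id covering every sample.
#' @return Object of the same class with one column per case, in first-seen
#'   case order.
#' @export
setGeneric("averageDuplicates",
           function(x, caseOf) standardGeneric("averageDuplicates"))

#' @rdname averageDuplicates
#' @export
setMethod("averageDuplicates", "matrix", function(x, caseOf) {
  if (ncol(x) == 0) return(x)
  missing <- setdiff(colnames(x), names(caseOf))
  if (length(missing))
    stopf("samples not mapped to a case: %s", paste(missing, collapse = ", "))
  cases <- caseOf[colnames(x)]
  out <- sapply(unique(cases), function(cs) {
    cols <- x[, cases == cs, drop = FALSE]
    if (ncol(cols) == 1) cols[, 1] else round(rowMeans(cols))
  })
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), unique(cases)))
  out
})

#' @rdname averageDuplicates
#' @export
setMethod("averageDuplicates", "UBCCohort", function(x, caseOf) {
  cnt <- averageDuplicates(cohortCounts(x), caseOf)
  cases <- caseOf[colnames(x)]
  first <- match(unique(cases), cases)
  cd <- SummarizedExperiment::colData(x)[first, , drop = FALSE]
  rownames(cd) <- unique(cases)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt),
    rowData = SummarizedExperiment::rowData(x), colData = cd,
    metadata = S4Vectors::metadata(x))
  methods::new("UBCCohort", se)
})

# Reference column for TMM: sample whose 75th-percentile count fraction is
# closest to the mean across samples.
tmmReference <- function(counts, libsizes) {
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / libsizes
  which.min(abs(f75 - mean(f75)))
}

#' Trimmed-mean-of-M-values library-size factors
#'
#' Computes TMM normalization factors (via edgeR's implementation of the
#' published estimator): per-gene log ratios M and average log abundances A
#' against a reference sample, double trimming (default 30 percent of M,
#' 5 percent of A), and an inverse delta-method-variance weighted mean of
#' the surviving M values. Factors are rescaled to geometric mean 1.
#'
#' @param x Count matrix or [UBCCohort-class]; at least two samples.
#' @param trimM,trimA Trim proportions for M and A values.
#' @return A [TMMResult-class].
#' @export
setGeneric("tmmFactors",
           function(x, trimM = 0.30, trimA = 0.05) standardGeneric("tmmFactors"))

#' @rdname tmmFactors
#' @export
setMethod("tmmFactors", "matrix", function(x, trimM = 0.30, trimA = 0.05) {
  if (ncol(x) < 2) stopf("TMM needs at least two samples")
  libsizes <- colSums(x)
  ref <- tmmReference(x, libsizes)
  shared <- vapply(seq_len(ncol(x)), function(j)
    any(x[, j] > 0 & x[, ref] > 0), logical(1))
  if (!all(shared))
    stopf("sample(s) share no positive genes with the reference: %s",
          paste(colnames(x)[!shared], collapse = ", "))
  f <- edgeR::calcNormFactors(x, method = "TMM", logratioTrim = trimM,
                              sumTrim = trimA)
  if (any(!is.finite(f))) stopf("TMM factors undefined for: %s",
                                paste(colnames(x)[!is.finite(f)],
                                      collapse = ", "))
  methods::new("TMMResult",
               factors = setNames(as.numeric(f), colnames(x)),
               referenceSample = colnames(x)[ref],
               trimM = trimM, trimA = trimA)
})

#' @rdname tmmFactors
#' @export
setMethod("tmmFactors", "UBCCohort", function(x, trimM = 0.30, trimA = 0.05) {
  tmmFactors(cohortCounts(x), trimM = trimM, trimA = trimA)
})

#' log2-RPKM expression values
#'
#' `log2((count + pseudocount) / (effLib_s / 1e6 * length_g / 1e3))` with
#' effective library size = column sum times the TMM factor.
#'
#' @param x Count matrix or [UBCCohort-class].
#' @param tmm A [TMMResult-class] aligned with the samples; NULL for unit
#'   factors.
#' @param geneLengths Gene lengths in bp (taken from the cohort when `x` is
#'   a [UBCCohort-class]).
#' @param pseudocount Prior count, default 0.5.
#' @return An [ExpressionMatrix-class].
#' @export
setGeneric("log2RPKM", function(x, tmm = NULL, geneLengths = NULL,
                                pseudocount = 0.5) standardGeneric("log2RPKM"))

#' @rdname log2RPKM
#' @export
setMethod("log2RPKM", "matrix", function(x, tmm = NULL, geneLengths = NULL,
                                         pseudocount = 0.5) {
  if (is.null(geneLengths)) stopf("gene lengths are required for RPKM")
  if (length(geneLengths) != nrow(x)) stopf("gene lengths misaligned")
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  factors <- if (is.null(tmm)) rep(1, ncol(x)) else {
    if (!setequal(names(normFactors(tmm)), colnames(x)))
      stopf("TMM factors do not align with the samples")
    normFactors(tmm)[colnames(x)]
  }
  libsizes <- colSums(x)
  if (any(libsizes <= 0)) stopf("zero library size in sample(s): %s",
                                paste(colnames(x)[libsizes <= 0],
                                      collapse = ", "))
  effLib <- libsizes * factors
  denom <- outer(geneLengths / 1e3, effLib / 1e6)
  vals <- log2((x + pseudocount) / denom)
  methods::new("ExpressionMatrix", values = vals, transform = "log2_rpkm",
               pseudocount = pseudocount,
               effectiveLibsizes = setNames(effLib, colnames(x)))
})

#' @rdname log2RPKM
#' @export
setMethod("log2RPKM", "UBCCohort", function(x, tmm = NULL, geneLengths = NULL,
                                            pseudocount = 0.5) {
  log2RPKM(cohortCounts(x), tmm = tmm,
           geneLengths = as.numeric(cohortLengths(x)),
           pseudocount = pseudocount)
})

#' log-CPM expression values
#'
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)`.
#'
#' @param x Count matrix or [UBCCohort-class].
#' @param prior Prior count, default 0.5.
#' @return An [ExpressionMatrix-class].
#' @export
setGeneric("logCPM", function(x, prior = 0.5) standardGeneric("logCPM"))

#' @rdname logCPM
#' @export
setMethod("logCPM", "matrix", function(x, prior = 0.5) {
  if (prior < 0) stopf("prior must be >= 0")
  libsizes <- colSums(x)
  if (any(libsizes <= 0)) stopf("zero library size in sample(s): %s",
                                paste(colnames(x)[libsizes <= 0],
                                      collapse = ", "))
  vals <- log2(sweep(x + prior, 2, libsizes + 2 * prior, `/`) * 1e6)
  methods::new("ExpressionMatrix", values = vals, transform = "log_cpm",
               pseudocount = prior,
               effectiveLibsizes = setNames(libsizes, colnames(x)))
})

#' @rdname logCPM
#' @export
setMethod("logCPM", "UBCCohort", function(x, prior = 0.5) {
  logCPM(cohortCounts(x), prior = prior)
})

#' Write / read an expression matrix as TSV
#'
#' The writer records the transform and pseudocount in a one-line `#` header
#' comment; the reader restores them.
#'
#' @param em An [ExpressionMatrix-class].
#' @param path TSV path.
#' @return `writeExpressionMatrix` the path, invisibly;
#'   `readExpressionMatrix` an [ExpressionMatrix-class].
#' @export
writeExpressionMatrix <- function(em, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# transform=%s pseudocount=%g",
                     exprTransform(em), em@pseudocount), con)
  df <- data.frame(gene_id = rownames(exprValues(em)), exprValues(em),
                   check.names = FALSE, row.names = NULL)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr,
    regexec("transform=(\\S+) pseudocount=(\\S+)", hdr))[[1]]
  if (length(meta) != 3) stopf("missing transform header comment")
  df <- read.delim(path, skip = 1, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene_id
  methods::new("ExpressionMatrix", values = vals, transform = meta[2],
               pseudocount = as.numeric(meta[3]),
               effectiveLibsizes = rep(NA_real_, ncol(vals)))
}
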