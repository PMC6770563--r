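# Internal helpers shared across modules.

# Deterministically expand one user seed into named per-stage seeds.
# Values stay well below 2^31.
expandSeed <- function(seed, stages) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max %/% 4, length(stages)), stages)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Run expr with a local RNG state seeded at `seed`, restoring state after.
withSeed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Counts assay of a UBCCohort, plain matrix.
cohortCounts <- function(cohort) {
  SummarizedExperiment::assay(cohort, "counts")
}

# Gene lengths in bp, named.
cohortLengths <- function(cohort) {
  setNames(SummarizedExperiment::rowData(cohort)$length_bp, rownames(cohort))
}

# colData as a plain data.frame with sample_id column first.
cohortAnnotation <- function(cohort) {
  df <- as.data.frame(SummarizedExperiment::colData(cohort))
  cbind(sample_id = colnames(cohort), df, row.names = NULL,
        stringsAsFactors = FALSE)
}
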