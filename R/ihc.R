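#' Four-tier immunohistochemistry scoring
#'
#' Converts percent-positive-tumor-cell values to the semi-quantitative
#' tier score. Standard markers (pSTAT3, CK5/6, CK14, CK20, MYC, FOSL1):
#' `[0,5) -> 0, [5,25) -> 1, [25,50) -> 2, [50,100] -> 3`. UPK2 uses the
#' lower positivity cut-offs of a terminal-differentiation marker: 0 only
#' for a fully negative stain, `(0,10) -> 1, [10,25) -> 2, [25,100] -> 3`.
#' Interval boundaries are half-open with the printed ">=" anchors honored.
#'
#' @param percent Percent positive tumor cells, in \[0, 100\] (vectorized).
#' @param marker Marker name; `"UPK2"` switches to the UPK2 scale.
#' @return Integer tier(s) in 0..3.
#' @export
quantizeScore <- function(percent, marker = "CK5_6") {
  if (any(percent < 0 | percent > 100)) stopf("percent must be in [0, 100]")
  if (identical(marker, "UPK2")) {
    ifelse(percent == 0, 0L,
      ifelse(percent < 10, 1L, ifelse(percent < 25, 2L, 3L)))
  } else {
    ifelse(percent < 5, 0L,
      ifelse(percent < 25, 1L, ifelse(percent < 50, 2L, 3L)))
  }
}

#' Basal / luminal / non-type call from the four-marker panel
#'
#' Decision rules on tier scores, with basal and luminal criteria evaluated
#' independently:
#' \itemize{
#'   \item basal (i): CK5/6 or CK14 at score 3;
#'   \item basal (ii): CK5/6 and CK14 both at score 2 with luminal markers
#'     at score 0-1;
#'   \item luminal (i): CK20 at score 3, or UPK2 at score 2-3 with basal
#'     markers at score 0-1;
#'   \item luminal (ii): CK20 and UPK2 both at score 1-2 with basal markers
#'     at score 0-1.
#' }
#' Exactly one side true gives that call; both true gives non-type with
#' `conflict = TRUE`; neither gives non-type. (The published wording leaves
#' the attachment of the low-basal condition ambiguous; this convention is
#' a documented decision.)
#'
#' @param ck5_6,ck14,ck20,upk2 Tier scores in 0..3 (vectorized).
#' @return data.frame with `call` (basal/luminal/nontype), `rule_fired`
#'   and `conflict`.
#' @export
callSubtype <- function(ck5_6, ck14, ck20, upk2) {
  args <- list(CK5_6 = ck5_6, CK14 = ck14, CK20 = ck20, UPK2 = upk2)
  miss <- names(args)[vapply(args, function(a) any(is.na(a)) ||
                               length(a) == 0, logical(1))]
  if (length(miss))
    stopf("missing marker score(s): %s", paste(miss, collapse = ", "))
  if (any(unlist(args) < 0 | unlist(args) > 3 |
          unlist(args) != round(unlist(args))))
    stopf("tier scores must be integers in 0..3")

  basalLow <- ck5_6 <= 1 & ck14 <= 1
  luminalLow <- ck20 <= 1 & upk2 <= 1
  bI <- ck5_6 == 3 | ck14 == 3
  bII <- ck5_6 == 2 & ck14 == 2 & luminalLow
  lI <- ck20 == 3 | (upk2 >= 2 & basalLow)
  lII <- ck20 %in% 1:2 & upk2 %in% 1:2 & basalLow
  basal <- bI | bII
  luminal <- lI | lII

  call <- ifelse(basal & !luminal, "basal",
                 ifelse(luminal & !basal, "luminal", "nontype"))
  conflict <- basal & luminal
  rule <- ifelse(conflict, "conflict",
    ifelse(basal & bI, "basal_i",
    ifelse(basal, "basal_ii",
    ifelse(luminal & lI, "luminal_i",
    ifelse(luminal, "luminal_ii", "none")))))
  data.frame(call = call, rule_fired = rule, conflict = conflict,
             stringsAsFactors = FALSE)
}

#' Call subtypes for a whole IHC panel table
#'
#' Accepts percent columns (auto-quantized per marker) or ready tier
#' scores; adds per-marker tiers, the subtype call, the matched rule and
#' the conflict flag.
#'
#' @param panel data.frame with columns `CK5_6`, `CK14`, `CK20`, `UPK2`
#'   (and optionally further markers, carried through).
#' @param provenance `"percent"`, `"score"` or `"auto"` (scores are
#'   detected when every value is an integer in 0..3).
#' @return The input with `tier_*`, `call`, `rule_fired`, `conflict`
#'   columns appended.
#' @export
callSubtypePanel <- function(panel, provenance = c("auto", "percent",
                                                   "score")) {
  provenance <- match.arg(provenance)
  markers <- c("CK5_6", "CK14", "CK20", "UPK2")
  miss <- setdiff(markers, colnames(panel))
  if (length(miss))
    stopf("missing marker column(s): %s", paste(miss, collapse = ", "))
  vals <- as.matrix(panel[, markers])
  if (provenance == "auto")
    provenance <- if (all(vals == round(vals) & vals >= 0 & vals <= 3))
      "score" else "percent"
  tiers <- if (provenance == "percent")
    sapply(markers, function(m) quantizeScore(panel[[m]], m))
  else vals
  tiers <- matrix(as.integer(tiers), nrow = nrow(panel),
                  dimnames = list(NULL, markers))
  calls <- callSubtype(tiers[, "CK5_6"], tiers[, "CK14"],
                       tiers[, "CK20"], tiers[, "UPK2"])
  colnames(tiers) <- paste0("tier_", markers)
  cbind(panel, tiers, calls)
}

#' High/low dichotomization of a tier score
#'
#' High means tier 2 or 3; low means 0 or 1.
#'
#' @param score Tier score(s) in 0..3.
#' @return `"high"` / `"low"` character vector.
#' @export
dichotomize <- function(score) {
  if (any(!score %in% 0:3)) stopf("tier scores must be integers in 0..3")
  ifelse(score >= 2, "high", "low")
}

#' Two-by-two contingency test
#'
#' Pearson chi-square without continuity correction (default, recorded in
#' the output), Yates-corrected chi-square, or Fisher's exact test.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param method `"pearson"`, `"yates"` or `"fisher"`.
#' @return list with `statistic` (NA for Fisher), `p_value`, `method`.
#' @export
contingencyTest <- function(table, method = c("pearson", "yates",
                                              "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stopf("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stopf("cells must be non-negative integers")
  res <- switch(method,
    pearson = {
      ct <- suppressWarnings(chisq.test(table, correct = FALSE))
      if (any(ct$expected <= 0)) stopf("expected cell counts must be > 0")
      list(statistic = unname(ct$statistic), p_value = ct$p.value)
    },
    yates = {
      ct <- suppressWarnings(chisq.test(table, correct = TRUE))
      list(statistic = unname(ct$statistic), p_value = ct$p.value)
    },
    fisher = {
      ft <- fisher.test(table)
      list(statistic = NA_real_, p_value = ft$p.value)
    })
  c(res, method = method)
}
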