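# Independently coded brute-force oracles. Each is a direct transcription
# of the published definition, deliberately naive, and shares no code with
# the implementation under test.

# TMM: M/A values against the 75th-percentile-matched reference, double
# rank trimming, inverse delta-method-variance weighted mean, geometric
# rescaling.
tmmOracle <- function(counts, trimM = 0.3, trimA = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- sapply(seq_len(ncol(counts)), function(j) {
    p <- counts[, j] / lib[j]
    pr <- counts[, ref] / lib[ref]
    keep <- counts[, j] > 0 & counts[, ref] > 0
    M <- log2(p[keep] / pr[keep])
    A <- 0.5 * log2(p[keep] * pr[keep])
    if (max(abs(M)) < 1e-6) return(1)
    w <- (lib[j] - counts[keep, j]) / (lib[j] * counts[keep, j]) +
      (lib[ref] - counts[keep, ref]) / (lib[ref] * counts[keep, ref])
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    k2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[k2] / w[k2]) / sum(1 / w[k2]))
  })
  f / exp(mean(log(f)))
}

# Product-limit estimator written out longhand (no survival::).
kmOracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    atRisk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / atRisk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

kmOracleAt <- function(km, u, left = FALSE) {
  sel <- if (left) km$time < u else km$time <= u
  if (!any(sel)) 1 else km$surv[max(which(sel))]
}

# IPCW Brier score as a literal sum over samples, with the censoring KM
# built by kmOracle on the flipped indicator.
brierOracle <- function(time, event, S, t) {
  G <- kmOracle(time, 1 - event)
  total <- 0
  for (i in seq_along(time)) {
    if (time[i] <= t && event[i] == 1)
      total <- total + S[i]^2 / kmOracleAt(G, time[i], left = TRUE)
    else if (time[i] > t)
      total <- total + (1 - S[i])^2 / kmOracleAt(G, t)
  }
  total / length(time)
}

# Four-marker subtype decision, re-transcribed clause by clause from the
# published wording with the package's documented attachment convention
# (low-basal condition on the UPK2 arm and on luminal clause ii).
subtypeOracle <- function(ck56, ck14, ck20, upk2) {
  basal <- (ck56 == 3 || ck14 == 3) ||
    (ck56 == 2 && ck14 == 2 && ck20 <= 1 && upk2 <= 1)
  lowBasal <- ck56 <= 1 && ck14 <= 1
  luminal <- (ck20 == 3) ||
    (upk2 %in% c(2, 3) && lowBasal) ||
    (ck20 %in% c(1, 2) && upk2 %in% c(1, 2) && lowBasal)
  if (basal && luminal) c(call = "nontype", conflict = TRUE)
  else if (basal) c(call = "basal", conflict = FALSE)
  else if (luminal) c(call = "luminal", conflict = FALSE)
  else c(call = "nontype", conflict = FALSE)
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration.
fisherOracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  pObs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
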