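# Independent brute-force oracles. These deliberately avoid the package's
# recursive/vectorised code paths: contributions come from explicit prefix
# enumeration, similarities from double loops.

codePrefixes <- function(code) {
  seg <- strsplit(code, ".", fixed = TRUE)[[1]]
  vapply(seq_along(seg), function(k) paste(seg[1:k], collapse = "."), character(1))
}

# DS1 via path enumeration: a node's contribution is delta^(shortest number
# of segments from the node down to any full code it prefixes)
oracleDS1 <- function(codes, delta = 0.5) {
  nodes <- unique(unlist(lapply(codes, codePrefixes)))
  nseg <- function(x) length(strsplit(x, ".", fixed = TRUE)[[1]])
  vals <- vapply(nodes, function(u) {
    dists <- vapply(codes, function(tc) {
      if (u == tc || startsWith(tc, paste0(u, "."))) nseg(tc) - nseg(u) else NA_integer_
    }, numeric(1))
    delta^min(dists, na.rm = TRUE)
  }, numeric(1))
  names(vals) <- nodes
  vals
}

oracleDISSS1 <- function(codesI, codesJ, delta = 0.5) {
  if (length(codesI) == 0 || length(codesJ) == 0) return(0)
  ci <- oracleDS1(codesI, delta); cj <- oracleDS1(codesJ, delta)
  shared <- intersect(names(ci), names(cj))
  if (length(shared) == 0) return(0)
  sum(ci[shared] + cj[shared]) / (sum(ci) + sum(cj))
}

# DISSS2 oracle over a list of code vectors (one element per disease)
oracleDISSS2 <- function(codesList, i, j, negLog = TRUE) {
  nodeSets <- lapply(codesList, function(cs) unique(unlist(lapply(cs, codePrefixes))))
  if (length(nodeSets[[i]]) == 0 || length(nodeSets[[j]]) == 0) return(0)
  allTerms <- unique(unlist(nodeSets))
  ic <- vapply(allTerms, function(t)
    log(sum(vapply(nodeSets, function(s) t %in% s, logical(1))) / length(codesList)),
    numeric(1))
  if (negLog) ic <- -ic
  names(ic) <- allTerms
  d2i <- sum(ic[nodeSets[[i]]]); d2j <- sum(ic[nodeSets[[j]]])
  if (d2i + d2j == 0) return(if (i == j) 1 else 0)
  shared <- intersect(nodeSets[[i]], nodeSets[[j]])
  if (length(shared) == 0) return(0)
  2 * sum(ic[shared]) / (d2i + d2j)
}

# best-match-average functional similarity, explicit double loop
oracleLNCFS <- function(setP, setQ, S) {
  if (length(setP) == 0 || length(setQ) == 0) return(0)
  bm <- function(d, set) max(vapply(set, function(e) S[d, e], numeric(1)))
  tot <- sum(vapply(setP, bm, numeric(1), set = setQ)) +
    sum(vapply(setQ, bm, numeric(1), set = setP))
  tot / (length(setP) + length(setQ))
}

oracleGIP <- function(profiles, muPrime = 0.5, divide = TRUE) {
  meanNorm <- mean(apply(profiles, 1, function(u) sum(u^2)))
  mu <- if (divide) muPrime / meanNorm else muPrime * meanNorm
  n <- nrow(profiles)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- exp(-mu * sum((profiles[i, ] - profiles[j, ])^2))
  out
}

# Mann-Whitney AUC by full pair enumeration (ties count 1/2)
oracleAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) for (n in neg)
    conc <- conc + (p > n) + 0.5 * (p == n)
  conc / (length(pos) * length(neg))
}

oracleMetrics <- function(TP, FP, TN, FN) {
  den <- sqrt((TP + FN) * (TP + FP) * (TN + FN) * (TN + FP))
  list(Acc = (TP + TN) / (TP + FN + TN + FP),
       Sen = if (TP + FN > 0) TP / (TP + FN) else 0,
       Spe = if (TN + FP > 0) TN / (TN + FP) else 0,
       Pre = if (TP + FP > 0) TP / (TP + FP) else 0,
       MCC = if (den > 0) (TP * TN - FP * FN) / den else 0)
}

# random tree-code hierarchy: nDiseases diseases, codes drawn as random
# paths of a small alphabet (shared prefixes arise naturally)
randomHierarchy <- function(nDiseases, maxDepth = 4, alphabet = c("A", "B", "C"),
                            pTwoCodes = 0.3) {
  draw <- function() paste(sample(alphabet, sample.int(maxDepth, 1), replace = TRUE),
                           collapse = ".")
  records <- lapply(seq_len(nDiseases), function(i) {
    codes <- draw()
    if (stats::runif(1) < pTwoCodes) codes <- unique(c(codes, draw()))
    codes
  })
  names(records) <- paste0("dis", seq_len(nDiseases))
  new("DiseaseHierarchy", records = records)
}

# small configuration for protocol unit tests (not the benchmark conditions)
tinyConfig <- function(...) {
  pipelineConfig(latentDim = 8L, epochs = 10L, batchSize = 32L,
                 nTrees = 20L, ...)
}

tinyBundle <- function(seed = 3L) {
  generateBundle(syntheticSpec(nDiseases = 12L, nLncrnas = 20L, nClusters = 4L,
                               pIn = 0.7, pOut = 0.02, branching = 2L,
                               depth = 2L, seed = seed))
}
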