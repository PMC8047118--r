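# shared fixture builders; everything is generated in code at test time

toyMeta <- function(ids, condition = "NF", stage = "none", replicate = NULL) {
  n <- length(ids)
  data.frame(sample_id = ids,
             condition = rep_len(condition, n),
             stage = rep_len(stage, n),
             replicate = if (is.null(replicate)) seq_len(n)
                         else rep_len(replicate, n))
}

toyExpr <- function(counts, condition = "NF", stage = "none") {
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  ExpressionMatrix(counts, toyMeta(colnames(counts), condition, stage))
}

# one-column call set from vectors (0-based positions)
toyCalls <- function(pos, meth, total, sample_id = "s1", condition = "other",
                     stage = "none", replicate = 1L, chrom = "chr1") {
  MethylationCallSet(rep(chrom, length(pos)), pos,
                     matrix(as.integer(meth), ncol = 1),
                     matrix(as.integer(total), ncol = 1),
                     toyMeta(sample_id, condition, stage, replicate))
}

# hypergeometric upper tail by direct combinatorial enumeration
oracleHyper <- function(k, nA, nB, N) {
  j <- k:min(nA, nB)
  sum(choose(nA, j) * choose(N - nA, nB - j)) / choose(N, nB)
}

# two-sided Fisher exact p by enumeration over all tables with fixed margins
oracleFisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1), 0)
  pobs <- probs[a - lo + 1L]
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

adjustedRandIndex <- function(x, y) mclust::adjustedRandIndex(x, y)
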