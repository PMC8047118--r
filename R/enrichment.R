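#' Hypergeometric over-representation test
#'
#' Upper-tail probability P(X >= k) of drawing k or more members of a size
#' nA set when nB items are drawn without replacement from a universe of N
#' containing the set — the standard set-overlap enrichment test. k = 0
#' gives p = 1 exactly. \code{lower = TRUE} gives the under-representation
#' tail P(X <= k).
#'
#' @param k overlap count.
#' @param nA,nB sizes of the two sets.
#' @param N universe size.
#' @param lower use the lower tail.
#' @return p-value.
#' @export
#' @examples
#' hypergeomTest(4, 5, 5, 20)
hypergeomTest <- function(k, nA, nB, N, lower = FALSE) {
  if (nA > N || nB > N) stop("set sizes exceed the universe")
  if (k > min(nA, nB) || k < 0) stop("k must lie in [0, min(nA, nB)]")
  if (lower) stats::phyper(k, nA, N - nA, nB)
  else stats::phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE)
}

#' Representation factor: observed / expected overlap
#'
#' rf = k / (nA * nB / N), the observed overlap divided by the overlap
#' expected when the sets are independent.
#'
#' @inheritParams hypergeomTest
#' @return rf >= 0.
#' @export
#' @examples
#' representationFactor(30, 100, 60, 1000)  # 5
representationFactor <- function(k, nA, nB, N) {
  if (nA <= 0 || nB <= 0 || N <= 0) stop("nA, nB, N must be positive")
  k / (nA * nB / N)
}

#' Over-representation score
#'
#' Combines the representation factor and the hypergeometric p-value as
#' log2(rf) * (-log10(p)), so that enrichment (rf > 1, small p) scores
#' positive and depletion negative; rf = 1 or p = 1 give 0. With
#' \code{literal = TRUE} the factor is log10(p) itself (sign inverted).
#'
#' @param rf representation factor (> 0; rf = 0 returns -Inf with a
#'   warning).
#' @param p p-value in (0, 1].
#' @param literal use log10(p) instead of -log10(p).
#' @return Numeric score.
#' @export
overrepresentationScore <- function(rf, p, literal = FALSE) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  if (any(rf < 0)) stop("rf must be >= 0")
  if (any(rf == 0)) warning("rf = 0: score is -Inf")
  s <- log2(rf) * log10(p)
  if (literal) s else -s
}

#' Overlap enrichment of two sets in a universe
#'
#' Convenience wrapper computing overlap k, the hypergeometric p, the
#' representation factor and the over-representation score for two id
#' vectors.
#'
#' @param hits,set character id vectors (deduplicated, intersected with
#'   the universe).
#' @param universe character universe ids.
#' @return list: k, nA, nB, N, p, rf, ors.
#' @export
enrichTest <- function(hits, set, universe) {
  universe <- unique(universe)
  hits <- intersect(unique(hits), universe)
  set <- intersect(unique(set), universe)
  k <- length(intersect(hits, set))
  p <- hypergeomTest(k, length(hits), length(set), length(universe))
  rf <- representationFactor(k, length(hits), length(set), length(universe))
  list(k = k, nA = length(hits), nB = length(set), N = length(universe),
       p = p, rf = rf,
       ors = if (rf > 0) overrepresentationScore(rf, p) else -Inf)
}

#' Paired t-tests with Holm adjustment
#'
#' Two-sided paired t-test per comparison, Holm step-down adjustment across
#' the family. When every paired difference is exactly zero the test is
#' degenerate and p = 1 by convention.
#'
#' @param comparisons a named list; each element a list/data.frame with
#'   numeric vectors \code{x} and \code{y} of equal length (>= 2 pairs).
#' @return data.frame: comparison, t, pvalue, padj.
#' @export
pairedTHolm <- function(comparisons) {
  res <- lapply(comparisons, function(cm) {
    x <- cm$x; y <- cm$y
    if (length(x) != length(y) || length(x) < 2L)
      stop("each comparison needs >= 2 pairs of equal length")
    d <- x - y
    if (all(d == 0)) return(c(t = 0, pvalue = 1))
    # numerically constant nonzero difference: perfect separation (same
    # degeneracy threshold t.test itself applies)
    if (stats::sd(d) <= 10 * .Machine$double.eps * abs(mean(d)))
      return(c(t = sign(mean(d)) * Inf, pvalue = 0))
    tt <- stats::t.test(x, y, paired = TRUE)
    c(t = unname(tt$statistic), pvalue = tt$p.value)
  })
  m <- do.call(rbind, res)
  nm <- if (is.null(names(comparisons))) as.character(seq_along(comparisons))
        else names(comparisons)
  data.frame(comparison = nm, t = m[, "t"], pvalue = m[, "pvalue"],
             padj = stats::p.adjust(m[, "pvalue"], method = "holm"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement, as used
#' for the differential-expression thresholds.
#'
#' @param p numeric p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
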