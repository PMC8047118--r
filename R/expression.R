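#' RPM normalization: log2(RPM + 1)
#'
#' Normalized expression is \code{log2(count / librarySize * 1e6 + 1)},
#' with library size the column sum. Monotone in counts within a sample;
#' per-sample RPM values sum to 1e6.
#'
#' @param x an \linkS4class{ExpressionMatrix} (returns the object with a
#'   \code{norm} assay attached) or a plain count matrix (returns the
#'   normalized matrix).
#' @return Same class as \code{x}.
#' @export
#' @examples
#' normalizeRpm(matrix(c(0, 1, 99), 3, 1))
setGeneric("normalizeRpm", function(x) standardGeneric("normalizeRpm"))

#' @rdname normalizeRpm
#' @export
setMethod("normalizeRpm", "matrix", function(x) {
  cs <- colSums(x)
  if (any(cs == 0)) stop("zero library size in column(s): ",
                         paste(which(cs == 0), collapse = ", "))
  log2(sweep(x, 2L, cs, "/") * 1e6 + 1)
})

#' @rdname normalizeRpm
#' @export
setMethod("normalizeRpm", "ExpressionMatrix", function(x) {
  assays(x)$norm <- normalizeRpm(counts(x))
  validObject(x)
  x
})

#' Expressed-gene filter
#'
#' Keeps genes whose normalized expression exceeds 1 in at least one sample
#' (strictly; a gene at exactly 1 everywhere is dropped).
#'
#' @param x ExpressionMatrix with a \code{norm} assay, or a normalized
#'   matrix.
#' @param threshold strict lower bound, default 1.
#' @return Character vector of retained gene ids.
#' @export
filterExpressed <- function(x, threshold = 1) {
  nm <- if (is(x, "ExpressionMatrix")) normValues(x) else as.matrix(x)
  keep <- apply(nm, 1L, max) > threshold
  rownames(nm)[keep]
}

#' PCA of a normalized expression matrix
#'
#' Samples are observations in gene space; the input is centered per gene
#' and not scaled. Each component's loading vector is sign-flipped so its
#' largest-magnitude entry is positive, making results deterministic.
#'
#' @param norm gene x sample normalized matrix.
#' @param nComponents number of components to return (default
#'   \code{min(dim) } capped at samples - 1).
#' @return list with \code{scores} (sample x PC), \code{loadings}
#'   (gene x PC), \code{explainedVariance} (fraction per PC).
#' @export
pcaScoresLoadings <- function(norm, nComponents = NULL) {
  norm <- as.matrix(norm)
  ns <- ncol(norm)
  if (ns < 2L) stop("PCA needs at least 2 samples")
  kmax <- min(ns, nrow(norm))
  if (is.null(nComponents)) nComponents <- min(kmax, ns - 1L)
  if (nComponents > kmax)
    stop("requested ", nComponents, " components from a ", nrow(norm), " x ",
         ns, " matrix")
  X <- t(norm - rowMeans(norm))           # samples x genes, gene-centered
  sv <- svd(X, nu = nComponents, nv = nComponents)
  d <- sv$d[seq_len(nComponents)]
  loadings <- sv$v
  scores <- sv$u %*% diag(d, nComponents)
  # deterministic sign: largest |loading| entry positive per component
  for (j in seq_len(nComponents)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  tot <- sum(sv$d^2)
  dimnames(loadings) <- list(rownames(norm), paste0("PC", seq_len(nComponents)))
  dimnames(scores) <- list(colnames(norm), paste0("PC", seq_len(nComponents)))
  list(scores = scores, loadings = loadings,
       explainedVariance = if (tot > 0) d^2 / tot else rep(0, nComponents))
}

#' Select genes in the top fraction of absolute PC loadings
#'
#' Per requested component, genes whose |loading| reaches the top
#' \code{fraction} are taken (ties at the cutoff all included); the union
#' over components is returned.
#'
#' @param loadings gene x PC loading matrix from
#'   \code{\link{pcaScoresLoadings}}.
#' @param fraction top fraction per component, in (0, 1]; default 0.05.
#' @param components component indices, default \code{c(1, 2)}.
#' @return Character vector of selected gene ids.
#' @export
selectTopLoadingGenes <- function(loadings, fraction = 0.05,
                                  components = c(1L, 2L)) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (max(components) > ncol(loadings))
    stop("component ", max(components), " not present in loadings")
  sel <- character(0)
  for (j in components) {
    a <- abs(loadings[, j])
    ntop <- ceiling(fraction * length(a))
    cut <- sort(a, decreasing = TRUE)[ntop]
    sel <- union(sel, rownames(loadings)[a >= cut])
  }
  sel[order(match(sel, rownames(loadings)))]
}

# collapse replicate columns to stage means per condition; returns a
# gene x (condition.stage) matrix with stages in canonical order
.stageMeans <- function(norm, meta, conditions = NULL) {
  if (is.null(conditions))
    conditions <- intersect(c("NF", "NT", "SNT"), unique(meta$condition))
  cols <- list()
  for (cc in conditions) for (st in stageLevels()) {
    s <- meta$sample_id[meta$condition == cc & meta$stage == st]
    if (length(s) > 0L)
      cols[[paste(cc, st, sep = ".")]] <- rowMeans(norm[, s, drop = FALSE])
  }
  do.call(cbind, cols)
}

#' Cluster dynamically expressed genes and label trends
#'
#' Replicates are collapsed to stage means per condition, genes z-scored,
#' and Ward hierarchical clustering (Euclidean) cut at \code{k} clusters.
#' Each cluster is labelled from the successive stage-mean differences of
#' its centroid in the reference condition: \code{Pro} when no difference
#' falls below \code{-eps} and at least one exceeds \code{eps}, \code{Down}
#' for the mirror, else \code{Transient}.
#'
#' @param x ExpressionMatrix with \code{norm} assay.
#' @param genes gene ids to cluster (e.g. from
#'   \code{\link{selectTopLoadingGenes}}).
#' @param k number of clusters, default 6.
#' @param eps strictness threshold on a stage-mean difference, default 0.1
#'   normalized units.
#' @param condition reference condition for trend labelling, default the
#'   first of NF/NT/SNT present.
#' @return list with \code{assignment} (data.frame gene_id, cluster,
#'   trend), \code{clusterTrend} (named character), \code{centroids}
#'   (cluster x stage matrix, reference condition).
#' @export
clusterTrendGenes <- function(x, genes, k = 6L, eps = 0.1,
                              condition = NULL) {
  nm <- normValues(x)
  missing <- setdiff(genes, rownames(nm))
  if (length(missing) > 0L)
    stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  if (k > length(genes)) stop("k exceeds number of genes")
  meta <- sampleMeta(x)
  if (is.null(condition))
    condition <- intersect(c("NF", "NT", "SNT"), unique(meta$condition))[1L]
  sm <- .stageMeans(nm[genes, , drop = FALSE], meta)
  z <- t(apply(sm, 1L, function(v) {
    s <- stats::sd(v)
    if (s > 0) (v - mean(v)) / s else v - mean(v)
  }))
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  refcols <- paste(condition, stageLevels(), sep = ".")
  refcols <- refcols[refcols %in% colnames(sm)]
  centroids <- do.call(rbind, lapply(seq_len(k), function(i)
    colMeans(sm[cl == i, refcols, drop = FALSE])))
  rownames(centroids) <- seq_len(k)
  trend <- apply(centroids, 1L, function(v) {
    d <- diff(v)
    if (all(d >= -eps) && any(d > eps)) "Pro"
    else if (all(d <= eps) && any(d < -eps)) "Down"
    else "Transient"
  })
  list(assignment = data.frame(gene_id = genes, cluster = unname(cl),
                               trend = unname(trend[cl]),
                               stringsAsFactors = FALSE),
       clusterTrend = trend, centroids = centroids)
}

#' Differential expression calls under fixed thresholds
#'
#' The built-in statistic is a Welch two-sample t-test on log2(RPM+1)
#' replicate values per gene, with Benjamini-Hochberg adjustment; the fold
#' change is the difference of group means of normalized expression
#' (groupA - groupB). Alternatively a precomputed statistic table (columns
#' \code{gene_id, pvalue, lfc}, optionally \code{padj}) can be supplied via
#' \code{stats}, to which only the thresholds are applied. A gene is called
#' when adjusted p < \code{pThresh} and |lfc| > \code{lfcThresh}.
#'
#' @param x ExpressionMatrix with \code{norm} assay (ignored when
#'   \code{stats} is given, except for gene order).
#' @param groupA,groupB sample ids of the two groups (>= 2 each for the
#'   built-in test).
#' @param pThresh,lfcThresh calling thresholds, defaults 0.01 and 2.
#' @param stats optional external statistic table.
#' @return data.frame: gene_id, lfc, pvalue, padj, direction (up when
#'   groupA higher), significant.
#' @export
callDegs <- function(x, groupA = NULL, groupB = NULL, pThresh = 0.01,
                     lfcThresh = 2, stats = NULL) {
  if (!is.null(stats)) {
    need <- c("gene_id", "pvalue", "lfc")
    if (!all(need %in% colnames(stats)))
      stop("external stats table needs columns: ",
           paste(need, collapse = ", "))
    df <- as.data.frame(stats)
    if (!"padj" %in% colnames(df)) df$padj <- bhAdjust(df$pvalue)
  } else {
    nm <- normValues(x)
    bad <- setdiff(c(groupA, groupB), colnames(nm))
    if (length(bad) > 0L)
      stop("unknown sample(s): ", paste(bad, collapse = ", "))
    if (length(groupA) < 2L || length(groupB) < 2L)
      stop("need >= 2 replicates per group for the built-in test; supply ",
           "an externally computed statistic table via stats= instead")
    A <- nm[, groupA, drop = FALSE]; B <- nm[, groupB, drop = FALSE]
    mA <- rowMeans(A); mB <- rowMeans(B)
    vA <- apply(A, 1L, stats::var); vB <- apply(B, 1L, stats::var)
    nA <- length(groupA); nB <- length(groupB)
    se2 <- vA / nA + vB / nB
    tstat <- (mA - mB) / sqrt(se2)
    dfree <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    p <- 2 * stats::pt(-abs(tstat), dfree)
    p[!is.finite(tstat) & mA != mB] <- 0
    p[mA == mB] <- 1
    df <- data.frame(gene_id = rownames(nm), pvalue = p, lfc = mA - mB,
                     stringsAsFactors = FALSE)
    df$padj <- bhAdjust(df$pvalue)
  }
  df$direction <- ifelse(df$lfc > 0, "up", "down")
  df$significant <- df$padj < pThresh & abs(df$lfc) > lfcThresh
  rownames(df) <- NULL
  df[, c("gene_id", "lfc", "pvalue", "padj", "direction", "significant")]
}
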