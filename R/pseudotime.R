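#' Panel loading vector from a PCA on the NF samples
#'
#' lambda is the PC1 loading vector of a gene-centered, unscaled PCA of the
#' panel genes restricted to the NF samples. Because a principal-component
#' sign is arbitrary, lambda is flipped wholesale when the resulting
#' pseudotime decreases with the canonical NF stage order (Spearman < 0),
#' so that T increases along derivation.
#'
#' @param x ExpressionMatrix with \code{norm} assay, containing NF samples.
#' @param panel panel gene ids (all must be present).
#' @return Named numeric lambda, unit length, aligned to \code{panel}.
#' @export
computeLambda <- function(x, panel) {
  nm <- normValues(x)
  missing <- setdiff(panel, rownames(nm))
  if (length(missing) > 0L)
    stop("panel gene(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  meta <- sampleMeta(x)
  nf <- meta$sample_id[meta$condition == "NF"]
  if (length(nf) < 3L) stop("need >= 3 NF samples to derive lambda")
  sub <- nm[panel, nf, drop = FALSE]
  lambda <- pcaScoresLoadings(sub, nComponents = 1L)$loadings[, 1L]
  tt <- as.numeric(crossprod(sub, lambda))
  rho <- suppressWarnings(
    stats::cor(tt, stageIndex(meta$stage[match(nf, meta$sample_id)]),
               method = "spearman"))
  if (!is.na(rho) && rho < 0) lambda <- -lambda
  stats::setNames(lambda, panel)
}

#' Pseudotime of each replicate from a fixed panel
#'
#' T(replicate) = sum_i Exp_i * lambda_i over the panel, with Exp the
#' log2(RPM+1) normalized expression: a pure linear projection, no
#' re-fitting per replicate. The same NF-derived lambda is applied
#' unchanged to NT and SNT replicates.
#'
#' @param x ExpressionMatrix with \code{norm} assay.
#' @param panel panel gene ids.
#' @param lambda loading vector aligned to \code{panel} (e.g. from
#'   \code{\link{computeLambda}}).
#' @return A \linkS4class{PseudotimeResult}.
#' @export
inferPseudotime <- function(x, panel, lambda) {
  if (length(lambda) != length(panel))
    stop("lambda and panel lengths differ")
  nm <- normValues(x)
  missing <- setdiff(panel, rownames(nm))
  if (length(missing) > 0L)
    stop("panel gene(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  sub <- nm[panel, , drop = FALSE]
  if (anyNA(sub)) stop("NaN/NA normalized expression in panel genes")
  tt <- as.numeric(crossprod(sub, as.numeric(lambda)))
  new("PseudotimeResult", panel = as.character(panel),
      lambda = unname(as.numeric(lambda)),
      pseudotime = stats::setNames(tt, colnames(nm)))
}

#' Random-panel resampling null for the pseudotime
#'
#' Per iteration, \code{n} TFs are drawn without replacement from the TF
#' universe, lambda is re-derived on the NF samples for that random panel
#' (pseudotime inference is repeated in full, including the sign
#' convention), and T is computed for every replicate. Per-replicate mean,
#' sd and 5/95 percent quantiles over iterations are attached to the
#' result.
#'
#' @param result a \linkS4class{PseudotimeResult} from
#'   \code{\link{inferPseudotime}} (its panel size sets \code{n} unless
#'   given).
#' @param x ExpressionMatrix with \code{norm} assay.
#' @param tfUniverse candidate TF gene ids present in \code{x}.
#' @param n random panel size, default \code{length(panelGenes(result))}.
#' @param iterations number of random panels, default 5000.
#' @param seed integer seed; the run is reproducible given it.
#' @return \code{result} with null summaries filled in.
#' @export
nullPseudotime <- function(result, x, tfUniverse, n = NULL,
                           iterations = 5000L, seed = 1L) {
  stopifnot(is(result, "PseudotimeResult"))
  if (is.null(n)) n <- length(panelGenes(result))
  tfUniverse <- unique(as.character(tfUniverse))
  if (n > length(tfUniverse))
    stop("panel size ", n, " exceeds TF universe of ", length(tfUniverse))
  nm <- normValues(x)
  missing <- setdiff(tfUniverse, rownames(nm))
  if (length(missing) > 0L)
    stop("TF universe gene(s) missing from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  meta <- sampleMeta(x)
  nfIdx <- which(meta$condition == "NF")
  if (length(nfIdx) < 3L) stop("need >= 3 NF samples to derive lambda")
  nfStage <- stageIndex(meta$stage[nfIdx])
  # same math as computeLambda()/inferPseudotime(), on raw matrices
  Tmat <- .withSeed(seed, {
    vapply(seq_len(iterations), function(i) {
      pan <- sample(tfUniverse, n)
      sub <- nm[pan, nfIdx, drop = FALSE]
      sv <- svd(t(sub - rowMeans(sub)), nu = 0L, nv = 1L)
      lam <- sv$v[, 1L]
      if (lam[which.max(abs(lam))] < 0) lam <- -lam
      tnf <- as.numeric(crossprod(sub, lam))
      rho <- suppressWarnings(stats::cor(tnf, nfStage, method = "spearman"))
      if (!is.na(rho) && rho < 0) lam <- -lam
      as.numeric(crossprod(nm[pan, , drop = FALSE], lam))
    }, numeric(ncol(nm)))
  })                                       # replicates x iterations
  rownames(Tmat) <- colnames(nm)
  result@nullMean <- rowMeans(Tmat)
  result@nullSd <- apply(Tmat, 1L, stats::sd)
  result@nullQ05 <- apply(Tmat, 1L, stats::quantile, probs = 0.05)
  result@nullQ95 <- apply(Tmat, 1L, stats::quantile, probs = 0.95)
  names(result@nullMean) <- names(result@nullSd) <- rownames(Tmat)
  names(result@nullQ05) <- names(result@nullQ95) <- rownames(Tmat)
  result@nullIterations <- as.integer(iterations)
  result@seed <- as.integer(seed)
  validObject(result)
  result
}

#' Stage-ordering diagnostics of a pseudotime
#'
#' Reports the Spearman rank correlation between T and the canonical stage
#' index, per-stage Gaussian kernel densities of T (Silverman's
#' rule-of-thumb bandwidth), and adjacent-stage separation: the gap
#' \code{min(T next stage) - max(T current stage)}. Stages are fully
#' ordered when every adjacent gap is positive, i.e. every between-stage
#' gap exceeds the within-stage spread.
#'
#' @param T named numeric pseudotime per sample (e.g.
#'   \code{pseudotimes(result)}).
#' @param meta sample metadata with sample_id and stage.
#' @return list with \code{spearman}, \code{densities} (per stage; NULL
#'   when a stage has < 2 replicates), \code{gaps} (named numeric, one per
#'   adjacent stage pair) and \code{separated} (logical).
#' @export
stageOrderingDiagnostics <- function(T, meta) {
  meta <- as.data.frame(meta)
  idx <- stageIndex(meta$stage[match(names(T), meta$sample_id)])
  keep <- !is.na(idx)
  if (sum(keep) < 2L) stop("need >= 2 staged replicates")
  T <- T[keep]; idx <- idx[keep]
  if (length(unique(idx)) < 2L) stop("need >= 2 stages present")
  rho <- suppressWarnings(stats::cor(T, idx, method = "spearman"))
  present <- sort(unique(idx))
  dens <- lapply(present, function(i) {
    ti <- T[idx == i]
    if (length(ti) >= 2L && stats::sd(ti) > 0)
      stats::density(ti, bw = "nrd0") else NULL
  })
  names(dens) <- stageLevels()[present]
  gaps <- vapply(seq_len(length(present) - 1L), function(j)
    min(T[idx == present[j + 1L]]) - max(T[idx == present[j]]), 0)
  names(gaps) <- paste(stageLevels()[present[-length(present)]],
                       stageLevels()[present[-1L]], sep = "->")
  list(spearman = rho, densities = dens, gaps = gaps,
       separated = all(gaps > 0))
}

#' Does the resampling null order the stages?
#'
#' For each stage, pools the per-replicate iteration intervals
#' (5th-95th percentile of T over random panels) into one stage interval;
#' adjacent stages overlap when their intervals intersect. The null "fails
#' to order" the course when any adjacent pair overlaps.
#'
#' @param result PseudotimeResult with null summaries attached.
#' @param meta sample metadata with sample_id and stage.
#' @return list with \code{intervals} (stage x lo/hi), \code{overlaps}
#'   (logical per adjacent pair) and \code{ordered} (logical).
#' @export
nullStageSeparation <- function(result, meta) {
  ns <- nullSummary(result)
  meta <- as.data.frame(meta)
  idx <- stageIndex(meta$stage[match(ns$sample_id, meta$sample_id)])
  keep <- !is.na(idx)
  ns <- ns[keep, , drop = FALSE]; idx <- idx[keep]
  present <- sort(unique(idx))
  iv <- t(vapply(present, function(i)
    c(lo = min(ns$null_q05[idx == i]), hi = max(ns$null_q95[idx == i])),
    c(lo = 0, hi = 0)))
  rownames(iv) <- stageLevels()[present]
  ov <- vapply(seq_len(length(present) - 1L), function(j)
    max(iv[j, "lo"], iv[j + 1L, "lo"]) <= min(iv[j, "hi"], iv[j + 1L, "hi"]),
    TRUE)
  names(ov) <- paste(rownames(iv)[-nrow(iv)], rownames(iv)[-1L], sep = "->")
  list(intervals = iv, overlaps = ov, ordered = !any(ov))
}
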