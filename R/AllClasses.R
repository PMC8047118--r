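#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- colData rowRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' ExpressionMatrix: gene x sample counts with stage/condition metadata
#'
#' A \linkS4class{SummarizedExperiment} holding a non-negative integer
#' \code{counts} assay and, after \code{\link{normalizeRpm}}, a \code{norm}
#' assay of log2(RPM + 1) values. Column data carries \code{sample_id},
#' \code{condition} (NF/NT/SNT/CC/MII/other), \code{stage} (see
#' \code{\link{stageLevels}}) and \code{replicate}.
#'
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  if (!"counts" %in% names(assays(object)))
    return("assay 'counts' is required")
  cnt <- assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    return("counts must be non-negative integers")
  need <- c("sample_id", "condition", "stage", "replicate")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss) > 0L)
    return(paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if ("norm" %in% names(assays(object))) {
    nm <- assay(object, "norm")
    if (any(nm < 0)) return("norm must be >= 0")
    if (!all((nm == 0) == (cnt == 0)))
      return("norm == 0 must hold exactly where counts == 0")
  }
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param counts gene x sample matrix of non-negative integers with gene ids
#'   as rownames and sample ids as colnames.
#' @param meta data.frame with columns sample_id, condition, stage,
#'   replicate; one row per column of \code{counts}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
#' @examples
#' cnt <- matrix(rpois(6, 10), 3, 2,
#'               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), condition = "NF",
#'                    stage = c("TE3.5", "TE4.5"), replicate = 1L)
#' ExpressionMatrix(cnt, meta)
ExpressionMatrix <- function(counts, meta) {
  meta <- .checkSampleMeta(meta)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene_id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (is.null(colnames(counts))) colnames(counts) <- meta$sample_id
  if (!setequal(colnames(counts), meta$sample_id))
    stop("count columns do not match metadata sample_id set")
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = DataFrame(meta, row.names = meta$sample_id))
  new("ExpressionMatrix", se)
}

#' MethylationCallSet: per-CpG methylated/total counts per sample
#'
#' A \linkS4class{RangedSummarizedExperiment} with width-1 rows at the
#' 0-based plus-strand position of each CpG (stored 1-based internally, as
#' GRanges requires) and assays \code{meth} and \code{total}. \code{NA} in
#' both assays marks a CpG not detected in that sample, which is distinct
#' from a detected CpG with ratio 0.
#'
#' @export
setClass("MethylationCallSet", contains = "RangedSummarizedExperiment")

setValidity("MethylationCallSet", function(object) {
  if (!all(c("meth", "total") %in% names(assays(object))))
    return("assays 'meth' and 'total' are required")
  m <- assay(object, "meth"); t <- assay(object, "total")
  if (!identical(is.na(m), is.na(t)))
    return("meth and total must share the same missingness pattern")
  ok <- !is.na(m)
  if (any(m[ok] < 0) || any(t[ok] < 1))
    return("meth must be >= 0 and total >= 1 where detected")
  if (any(m[ok] > t[ok])) return("meth > total")
  if (length(object) > 0L && any(width(rowRanges(object)) != 1L))
    return("CpG rows must have width 1")
  TRUE
})

#' Construct a MethylationCallSet
#'
#' @param chrom,pos chromosome and 0-based plus-strand CpG position vectors.
#' @param meth,total matrices (CpG x sample) of methylated counts and
#'   coverage; NA where a CpG is not detected in a sample.
#' @param meta sample metadata data.frame (sample_id, condition, stage,
#'   replicate), one row per column.
#' @return A \linkS4class{MethylationCallSet}.
#' @export
MethylationCallSet <- function(chrom, pos, meth, total, meta) {
  meta <- .checkSampleMeta(meta)
  meth <- as.matrix(meth); total <- as.matrix(total)
  gr <- GRanges(chrom, IRanges(start = pos + 1L, width = 1L))
  o <- order(as.character(seqnames(gr)), start(gr))
  gr <- gr[o]
  meth <- meth[o, , drop = FALSE]; total <- total[o, , drop = FALSE]
  colnames(meth) <- colnames(total) <- meta$sample_id
  se <- SummarizedExperiment(
    assays = list(meth = meth, total = total), rowRanges = gr,
    colData = DataFrame(meta, row.names = meta$sample_id))
  new("MethylationCallSet", se)
}

#' CGIMethylationMatrix: CGI x sample methylation summaries
#'
#' A \linkS4class{RangedSummarizedExperiment} over CpG-island intervals with
#' assays \code{ratio} (unweighted mean of per-CpG ratios over detected
#' CpGs; NA where the island fails the detection filter), \code{pooledMeth}
#' and \code{pooledTotal} (count sums over detected CpGs, used for Fisher
#' tests), and \code{detectedCpgs}.
#'
#' @export
setClass("CGIMethylationMatrix", contains = "RangedSummarizedExperiment")

setValidity("CGIMethylationMatrix", function(object) {
  need <- c("ratio", "pooledMeth", "pooledTotal", "detectedCpgs")
  if (!all(need %in% names(assays(object))))
    return(paste0("assays required: ", paste(need, collapse = ", ")))
  r <- assay(object, "ratio")
  if (any(r[!is.na(r)] < 0 | r[!is.na(r)] > 1))
    return("ratio must lie in [0, 1]")
  pm <- assay(object, "pooledMeth"); pt <- assay(object, "pooledTotal")
  ok <- !is.na(pm)
  if (any(pm[ok] > pt[ok])) return("pooledMeth > pooledTotal")
  TRUE
})

#' Pseudotime of a derivation time course from a TF panel
#'
#' Holds the TF panel, its loading vector lambda (PC1 loadings of a PCA on
#' the NF samples, sign-fixed so pseudotime increases with NF stage), the
#' per-replicate pseudotime T = sum_i Exp_i * lambda_i, and, when the
#' resampling null has been run, per-replicate summaries of T over random
#' same-size panels.
#'
#' @slot panel character, panel gene ids.
#' @slot lambda numeric loading vector aligned to \code{panel}.
#' @slot pseudotime named numeric, T per sample.
#' @slot nullMean,nullSd,nullQ05,nullQ95 named numeric null summaries per
#'   sample (length 0 before \code{\link{nullPseudotime}}).
#' @slot nullIterations,seed integers describing the null run.
#' @export
setClass("PseudotimeResult",
  representation(panel = "character", lambda = "numeric",
                 pseudotime = "numeric", nullMean = "numeric",
                 nullSd = "numeric", nullQ05 = "numeric",
                 nullQ95 = "numeric", nullIterations = "integer",
                 seed = "integer"),
  prototype(nullMean = numeric(0), nullSd = numeric(0),
            nullQ05 = numeric(0), nullQ95 = numeric(0),
            nullIterations = 0L, seed = NA_integer_))

setValidity("PseudotimeResult", function(object) {
  if (length(object@lambda) != length(object@panel))
    return("lambda and panel lengths differ")
  if (length(object@nullMean) > 0L &&
      !identical(names(object@nullMean), names(object@pseudotime)))
    return("null summaries must align with pseudotime samples")
  TRUE
})

#' Aberrant (AHM/ALM) CGI methylation calls versus a reference condition
#'
#' Per (CGI, stage) status in a test condition relative to the matched stage
#' of a reference condition: \code{AHM} when the test ratio exceeds the
#' reference by more than \code{delta}, \code{ALM} for the mirror, else
#' \code{normal}.
#'
#' @slot calls DataFrame with columns cgi, stage, status, plus the two
#'   ratios.
#' @slot condition,reference the compared conditions.
#' @slot delta numeric calling threshold.
#' @export
setClass("AberrantReport",
  representation(calls = "DataFrame", condition = "character",
                 reference = "character", delta = "numeric"))

setValidity("AberrantReport", function(object) {
  need <- c("cgi", "stage", "status")
  if (!all(need %in% colnames(object@calls)))
    return("calls needs columns cgi, stage, status")
  if (!all(object@calls$status %in% c("AHM", "ALM", "normal")))
    return("status must be AHM, ALM or normal")
  if (anyDuplicated(paste(object@calls$cgi, object@calls$stage)))
    return("one status per (cgi, stage) required")
  TRUE
})
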