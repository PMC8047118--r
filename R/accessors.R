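#' @importFrom BiocGenerics counts
NULL

#' Accessors for tscdyn data classes
#'
#' \code{counts} returns the raw count assay; \code{normValues} the
#' log2(RPM+1) assay (error before \code{\link{normalizeRpm}});
#' \code{sampleMeta} the column metadata as a plain data.frame;
#' \code{methRatio} the per-entry meth/total ratio matrix;
#' \code{ratios} the CGI ratio assay.
#'
#' @param object a tscdyn data object.
#' @name accessors
#' @aliases counts,ExpressionMatrix-method
#' @return A matrix (assay accessors) or data.frame (\code{sampleMeta}).
NULL

#' @rdname accessors
#' @export
setMethod("counts", "ExpressionMatrix", function(object) {
  assay(object, "counts")
})

#' @rdname accessors
#' @export
setGeneric("normValues", function(object) standardGeneric("normValues"))

#' @rdname accessors
#' @export
setMethod("normValues", "ExpressionMatrix", function(object) {
  if (!"norm" %in% names(assays(object)))
    stop("no 'norm' assay yet; run normalizeRpm() first")
  assay(object, "norm")
})

#' @rdname accessors
#' @export
setGeneric("sampleMeta", function(object) standardGeneric("sampleMeta"))

#' @rdname accessors
#' @export
setMethod("sampleMeta", "SummarizedExperiment", function(object) {
  as.data.frame(colData(object))
})

#' @rdname accessors
#' @export
setGeneric("methRatio", function(object) standardGeneric("methRatio"))

#' @rdname accessors
#' @export
setMethod("methRatio", "MethylationCallSet", function(object) {
  assay(object, "meth") / assay(object, "total")
})

#' @rdname accessors
#' @export
setGeneric("ratios", function(object) standardGeneric("ratios"))

#' @rdname accessors
#' @export
setMethod("ratios", "CGIMethylationMatrix", function(object) {
  assay(object, "ratio")
})

#' @rdname accessors
#' @param x a PseudotimeResult.
#' @export
pseudotimes <- function(x) {
  stopifnot(is(x, "PseudotimeResult"))
  x@pseudotime
}

#' @rdname accessors
#' @export
panelGenes <- function(x) {
  stopifnot(is(x, "PseudotimeResult"))
  x@panel
}

#' @rdname accessors
#' @export
lambdaWeights <- function(x) {
  stopifnot(is(x, "PseudotimeResult"))
  stats::setNames(x@lambda, x@panel)
}

#' @rdname accessors
#' @export
nullSummary <- function(x) {
  stopifnot(is(x, "PseudotimeResult"))
  if (length(x@nullMean) == 0L)
    stop("no resampling null attached; run nullPseudotime() first")
  data.frame(sample_id = names(x@nullMean), null_mean = unname(x@nullMean),
             null_sd = unname(x@nullSd), null_q05 = unname(x@nullQ05),
             null_q95 = unname(x@nullQ95))
}

#' @rdname accessors
#' @export
aberrantCalls <- function(x) {
  stopifnot(is(x, "AberrantReport"))
  as.data.frame(x@calls)
}

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  assays:", paste(names(assays(object)), collapse = ", "), "\n")
  md <- sampleMeta(object)
  cat("  conditions:", paste(sort(unique(md$condition)), collapse = ", "), "\n")
  cat("  stages:", paste(intersect(stageLevels(), md$stage), collapse = " < "),
      "\n")
})

setMethod("show", "MethylationCallSet", function(object) {
  det <- sum(!is.na(assay(object, "total")))
  cat("MethylationCallSet:", nrow(object), "CpGs x", ncol(object),
      "samples;", det, "detected calls\n")
})

setMethod("show", "CGIMethylationMatrix", function(object) {
  r <- assay(object, "ratio")
  cat("CGIMethylationMatrix:", nrow(object), "CGIs x", ncol(object),
      "samples;", sum(!is.na(r)), "retained ratios\n")
})

setMethod("show", "PseudotimeResult", function(object) {
  cat("PseudotimeResult: panel of", length(object@panel), "genes,",
      length(object@pseudotime), "samples\n")
  if (length(object@nullMean) > 0L)
    cat("  resampling null:", object@nullIterations, "iterations (seed",
        object@seed, ")\n")
})

setMethod("show", "AberrantReport", function(object) {
  tab <- table(object@calls$status)
  cat("AberrantReport:", object@condition, "vs", object@reference,
      "(delta", object@delta, ")\n  ")
  cat(paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
})
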