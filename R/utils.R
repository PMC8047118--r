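#' Canonical stage order of a TSC derivation time course
#'
#' The five sampled stages, from E3.5 trophectoderm to passaged TSC lines.
#' All stage-ordered computations (trend labelling, adjacent-stage deltas,
#' pseudotime diagnostics) use this fixed order.
#'
#' @return Character vector of stage labels in derivation order.
#' @export
#' @examples
#' stageLevels()
stageLevels <- function() {
  c("TE3.5", "TE4.5", "outgrowth", "TSC_P1", "TSC_Pn")
}

#' @rdname stageLevels
#' @param stage character vector of stage labels.
#' @return \code{stageIndex}: integer index (1-5) of each stage in the
#'   canonical order; NA for labels outside the course (e.g. \code{"none"}).
#' @export
stageIndex <- function(stage) {
  match(as.character(stage), stageLevels())
}

conditionLevels <- function() c("NF", "NT", "SNT", "CC", "MII", "other")

# validate a sample-metadata data.frame; returns it with factors normalized
.checkSampleMeta <- function(meta) {
  need <- c("sample_id", "condition", "stage", "replicate")
  miss <- setdiff(need, colnames(meta))
  if (length(miss) > 0L) {
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  meta <- as.data.frame(meta)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  }
  bad <- setdiff(unique(as.character(meta$condition)), conditionLevels())
  if (length(bad) > 0L) {
    stop("unknown condition value(s): ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(unique(as.character(meta$stage)),
                 c(stageLevels(), "none"))
  if (length(bad) > 0L) {
    stop("unknown stage value(s): ", paste(bad, collapse = ", "))
  }
  if (any(meta$replicate < 1 | meta$replicate != round(meta$replicate))) {
    stop("replicate must be a positive integer")
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$condition <- as.character(meta$condition)
  meta$stage <- as.character(meta$stage)
  meta$replicate <- as.integer(meta$replicate)
  meta
}

# deterministic TSV writer used by the CLI; fixed quoting/eol so reruns are
# byte-identical
.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
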