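#' Read a per-CpG bisulfite methylation report
#'
#' Reads the tabular output shape of a bisulfite methylation caller:
#' tab-separated \code{chrom, pos, strand, meth, total} with \code{pos}
#' 1-based and \code{strand} in \code{+}/\code{-}. Calls are normalized to
#' the 0-based plus-strand C of each CpG: a minus-strand call at file
#' position p describes the CpG whose plus-strand C sits at p-1, so it is
#' shifted and pooled with the matching plus-strand call by summing counts.
#' Pooling conserves total methylated and coverage sums.
#'
#' @param path file path; an optional header line naming the columns is
#'   skipped.
#' @param sample_id sample identifier for the resulting one-sample set.
#' @param condition,stage,replicate sample metadata (defaults
#'   \code{"other"}, \code{"none"}, 1).
#' @return A one-sample \linkS4class{MethylationCallSet}.
#' @export
readCpgReport <- function(path, sample_id, condition = "other",
                          stage = "none", replicate = 1L) {
  lines <- readLines(path)
  if (length(lines) > 0L && grepl("^chrom\t", lines[1L])) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  meta <- data.frame(sample_id = sample_id, condition = condition,
                     stage = stage, replicate = replicate)
  if (length(lines) == 0L) {
    return(MethylationCallSet(character(0), integer(0),
                              matrix(integer(0), 0, 1),
                              matrix(integer(0), 0, 1), meta))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L))
    stop("malformed CpG report row at line ", which(nf != 5L)[1L],
         " of ", path, " (expected 5 tab-separated fields)")
  m <- matrix(unlist(fields), ncol = 5L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  meth <- suppressWarnings(as.integer(m[, 4L]))
  total <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(total) |
                 !(m[, 3L] %in% c("+", "-")))
  if (length(bad) > 0L)
    stop("malformed CpG report row at line ", bad[1L], " of ", path)
  if (any(meth > total)) {
    i <- which(meth > total)[1L]
    stop("meth > total at line ", i, " of ", path)
  }
  if (any(total < 1L))
    stop("total coverage must be positive (line ",
         which(total < 1L)[1L], " of ", path, ")")
  # 1-based file -> 0-based; minus-strand C is one base 3' of the CpG's
  # plus-strand C
  pos0 <- pos - 1L - ifelse(m[, 3L] == "-", 1L, 0L)
  key <- paste(m[, 1L], pos0)
  meth <- as.integer(rowsum(meth, key, reorder = FALSE))
  total <- as.integer(rowsum(total, key, reorder = FALSE))
  first <- !duplicated(key)
  MethylationCallSet(m[first, 1L], pos0[first],
                     matrix(meth, ncol = 1L), matrix(total, ncol = 1L), meta)
}

#' Write one sample of a MethylationCallSet as a CpG report
#'
#' Detected CpGs are written as plus-strand, 1-based rows (the pooled
#' convention used internally), with a header line.
#'
#' @param mcs a \linkS4class{MethylationCallSet}.
#' @param path output file.
#' @param sample sample id to write (default: first column).
#' @return \code{path}, invisibly.
#' @export
writeCpgReport <- function(mcs, path, sample = colnames(mcs)[1L]) {
  m <- assay(mcs, "meth")[, sample]
  t <- assay(mcs, "total")[, sample]
  keep <- !is.na(t)
  df <- data.frame(chrom = as.character(seqnames(rowRanges(mcs)))[keep],
                   pos = start(rowRanges(mcs))[keep],  # 1-based out
                   strand = "+", meth = m[keep], total = t[keep])
  .writeTsv(df, path)
}

#' Read a gene-level count matrix
#'
#' TSV with header; first column \code{gene_id}, remaining columns sample
#' ids that must match the metadata sample set exactly.
#'
#' @param path counts TSV.
#' @param meta sample metadata data.frame (sample_id, condition, stage,
#'   replicate).
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readCounts <- function(path, meta) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "gene_id") stop("first column must be gene_id")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  cnt <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(cnt) || any(cnt != round(cnt)) || any(cnt < 0))
    stop("counts must be non-negative integers")
  rownames(cnt) <- df$gene_id
  ExpressionMatrix(cnt, meta)
}

#' @rdname readCounts
#' @param em an ExpressionMatrix.
#' @export
writeCounts <- function(em, path) {
  df <- data.frame(gene_id = rownames(em), counts(em), check.names = FALSE)
  .writeTsv(df, path)
}

#' Read a BED3/BED4 interval file
#'
#' BED is 0-based half-open; intervals are returned as a
#' \link[GenomicRanges]{GRanges} (1-based closed internally) sorted by
#' (chrom, start), with names taken from column 4 or auto-generated as
#' \code{region_<i>} in sorted order.
#'
#' @param path BED file.
#' @param prefix name prefix when the file has no name column.
#' @return A named \code{GRanges}.
#' @export
readBed <- function(path, prefix = "region") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED row with fewer than 3 fields at line ", which(nf < 3L)[1L])
  chrom <- vapply(fields, `[`, "", 1L)
  s <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(s) || anyNA(e))
    stop("non-integer BED coordinate at line ", which(is.na(s) | is.na(e))[1L])
  if (any(s >= e))
    stop("BED interval with start >= end at line ", which(s >= e)[1L])
  nm <- if (all(nf >= 4L)) vapply(fields, `[`, "", 4L) else NA_character_
  o <- order(chrom, s)
  gr <- GRanges(chrom[o], IRanges(s[o] + 1L, e[o]))
  names(gr) <- if (all(is.na(nm))) paste0(prefix, "_", seq_along(gr)) else nm[o]
  gr
}

#' @rdname readBed
#' @param gr a GRanges to write (0-based half-open on disk).
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                   end = end(gr),
                   name = if (is.null(names(gr)))
                     paste0("region_", seq_along(gr)) else names(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a flat TSS annotation table
#'
#' TSV with header \code{gene_id, chrom, tss, strand}; \code{tss} is the
#' 0-based transcript start position. When a gene has several records the
#' first listed transcript wins (with a message).
#'
#' @param path TSS table.
#' @return data.frame with one row per gene_id.
#' @export
readTss <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% colnames(df)))
    stop("TSS table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("TSS strand must be + or -")
  if (anyDuplicated(df$gene_id)) {
    message("TSS table: keeping first listed transcript per gene for ",
            sum(duplicated(df$gene_id)), " duplicate record(s)")
    df <- df[!duplicated(df$gene_id), , drop = FALSE]
  }
  df$tss <- as.integer(df$tss)
  rownames(df) <- NULL
  df[, need]
}
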