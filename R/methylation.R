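#' @importFrom GenomicRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

# biological-sample key of each column: condition_stage, or bare condition
# for course-external profiles (CC, MII)
.sampleKey <- function(meta) {
  ifelse(meta$stage == "none", meta$condition,
         paste(meta$condition, meta$stage, sep = "_"))
}

#' CpG coverage filter with replicate pooling
#'
#' A CpG is retained for a biological sample (condition x stage) when its
#' coverage reaches \code{minCov} in every replicate of that sample
#' (\code{mode = "all"}, the strict reading of a coverage > 4 filter) or in
#' at least one replicate (\code{mode = "any"}). Counts of the qualifying
#' replicates are then pooled by summation into one column per sample.
#'
#' @param mcs replicate-level \linkS4class{MethylationCallSet}.
#' @param minCov minimum per-replicate coverage, default 5.
#' @param mode \code{"all"} (default) or \code{"any"}.
#' @return A sample-level \linkS4class{MethylationCallSet}; undetected CpGs
#'   are NA.
#' @export
retainCpgs <- function(mcs, minCov = 5L, mode = c("all", "any")) {
  mode <- match.arg(mode)
  meta <- sampleMeta(mcs)
  key <- .sampleKey(meta)
  groups <- unique(key)
  m <- assay(mcs, "meth"); t <- assay(mcs, "total")
  nm <- nt <- matrix(NA_integer_, nrow(mcs), length(groups),
                     dimnames = list(NULL, groups))
  for (g in groups) {
    cols <- which(key == g)
    tg <- t[, cols, drop = FALSE]
    ok_rep <- !is.na(tg) & tg >= minCov
    keep <- if (mode == "all") rowSums(ok_rep) == length(cols)
            else rowSums(ok_rep) > 0L
    mg <- m[, cols, drop = FALSE]
    mg[!ok_rep] <- 0L; tg2 <- tg; tg2[!ok_rep] <- 0L; tg2[is.na(tg)] <- 0L
    mg[is.na(mg)] <- 0L
    nm[keep, g] <- as.integer(rowSums(mg)[keep])
    nt[keep, g] <- as.integer(rowSums(tg2)[keep])
  }
  first <- match(groups, key)
  outMeta <- data.frame(sample_id = groups,
                        condition = meta$condition[first],
                        stage = meta$stage[first], replicate = 1L,
                        stringsAsFactors = FALSE)
  gr <- rowRanges(mcs)
  MethylationCallSet(as.character(seqnames(gr)), start(gr) - 1L,
                     nm, nt, outMeta)
}

#' Aggregate CpG calls to CpG-island methylation
#'
#' CGI methylation is the unweighted mean of the per-CpG ratios of its
#' detected CpGs (not the pooled-count ratio); pooled count sums are kept
#' alongside for Fisher testing. A CGI is retained when its detected CpG
#' count reaches \code{minDetected} in every sample (\code{mode = "all"},
#' so ratios are comparable across stages) or in at least one sample
#' (\code{mode = "any"}). Overlapping CGIs are allowed but flagged with a
#' warning.
#'
#' @param mcs sample-level \linkS4class{MethylationCallSet} (from
#'   \code{\link{retainCpgs}}).
#' @param cgis named GRanges of CGI intervals.
#' @param minDetected minimum detected CpGs per CGI, default 5.
#' @param mode \code{"all"} (default) or \code{"any"}.
#' @return A \linkS4class{CGIMethylationMatrix} over the retained CGIs.
#' @export
cgiMethylation <- function(mcs, cgis, minDetected = 5L,
                           mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (is.null(names(cgis))) names(cgis) <- paste0("CGI_", seq_along(cgis))
  ovl <- findOverlaps(cgis, cgis)
  if (length(ovl) > length(cgis))
    warning("overlapping CGI intervals; CpGs in the overlap count toward ",
            "each island")
  hits <- findOverlaps(rowRanges(mcs), cgis)
  qi <- queryHits(hits); si <- subjectHits(hits)
  m <- assay(mcs, "meth"); t <- assay(mcs, "total")
  ncgi <- length(cgis); ns <- ncol(mcs)
  ratio <- matrix(NA_real_, ncgi, ns, dimnames = list(names(cgis), colnames(mcs)))
  pm <- pt <- det <- matrix(0L, ncgi, ns,
                            dimnames = list(names(cgis), colnames(mcs)))
  grp <- factor(si, levels = seq_len(ncgi))
  for (j in seq_len(ns)) {
    mm <- m[qi, j]; tt <- t[qi, j]
    ok <- !is.na(tt)
    det[, j] <- as.integer(tapply(ok, grp, sum, default = 0L))
    mm[!ok] <- 0L; tt0 <- tt; tt0[!ok] <- 0L
    pm[, j] <- as.integer(tapply(mm, grp, sum, default = 0L))
    pt[, j] <- as.integer(tapply(tt0, grp, sum, default = 0L))
    r <- mm / tt; r[!ok] <- NA
    ratio[, j] <- tapply(r, grp, mean, na.rm = TRUE, default = NA_real_)
  }
  ratio[det == 0L] <- NA
  keep <- if (mode == "all") rowSums(det >= minDetected) == ns
          else rowSums(det >= minDetected) > 0L
  se <- SummarizedExperiment(
    assays = list(ratio = ratio[keep, , drop = FALSE],
                  pooledMeth = pm[keep, , drop = FALSE],
                  pooledTotal = pt[keep, , drop = FALSE],
                  detectedCpgs = det[keep, , drop = FALSE]),
    rowRanges = cgis[keep], colData = colData(mcs))
  new("CGIMethylationMatrix", se)
}

#' Differentially methylated CGIs between two samples
#'
#' A CGI is called when the absolute methylation difference exceeds
#' \code{delta} and the two-sided Fisher exact p-value on the pooled
#' 2 x 2 count table (methylated / unmethylated in A vs B) is below
#' \code{alpha}. CGIs lacking a ratio in either sample are skipped with a
#' message.
#'
#' @param cgm a \linkS4class{CGIMethylationMatrix}.
#' @param sampleA,sampleB column names to compare.
#' @param delta methylation difference threshold, default 0.25.
#' @param alpha Fisher p threshold, default 0.05.
#' @return data.frame: cgi, ratioA, ratioB, diff, pvalue, called.
#' @export
differentialCgis <- function(cgm, sampleA, sampleB, delta = 0.25,
                             alpha = 0.05) {
  r <- ratios(cgm)
  if (!all(c(sampleA, sampleB) %in% colnames(r)))
    stop("unknown sample column")
  rA <- r[, sampleA]; rB <- r[, sampleB]
  ok <- !is.na(rA) & !is.na(rB)
  if (any(!ok))
    message(sum(!ok), " CGI(s) skipped: ratio missing in one sample")
  pm <- assay(cgm, "pooledMeth"); pt <- assay(cgm, "pooledTotal")
  idx <- which(ok)
  p <- vapply(idx, function(i) {
    tab <- matrix(c(pm[i, sampleA], pt[i, sampleA] - pm[i, sampleA],
                    pm[i, sampleB], pt[i, sampleB] - pm[i, sampleB]), 2L)
    stats::fisher.test(tab)$p.value
  }, 0)
  data.frame(cgi = rownames(r)[idx], ratioA = rA[idx], ratioB = rB[idx],
             diff = rA[idx] - rB[idx], pvalue = p,
             called = abs(rA[idx] - rB[idx]) > delta & p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Progressively changing (PHIM) CGIs and their K-means groups
#'
#' Within one condition's five-stage course, a CGI is PHIM when the largest
#' absolute adjacent-stage ratio difference exceeds \code{delta}
#' (\code{mode = "adjacent"}, the primary criterion) or when the global
#' max-minus-min ratio difference does (\code{mode = "global"}). PHIM CGIs
#' are grouped by K-means (fixed seed, \code{nstart} restarts, best
#' inertia) on their 4-vector of adjacent-stage deltas.
#'
#' @param cgm a \linkS4class{CGIMethylationMatrix} containing the
#'   condition's five stages.
#' @param condition condition whose course to analyse, default "NF".
#' @param delta ratio-difference threshold, default 0.25.
#' @param k number of K-means groups, default 5.
#' @param seed RNG seed for K-means.
#' @param nstart K-means restarts, default 10.
#' @param mode \code{"adjacent"} (default) or \code{"global"}.
#' @return data.frame: cgi, is_phim, group (NA unless PHIM), and the four
#'   adjacent-stage deltas.
#' @export
detectPhim <- function(cgm, condition = "NF", delta = 0.25, k = 5L,
                       seed = 1L, nstart = 10L,
                       mode = c("adjacent", "global")) {
  mode <- match.arg(mode)
  meta <- sampleMeta(cgm)
  cols <- vapply(stageLevels(), function(st) {
    i <- which(meta$condition == condition & meta$stage == st)
    if (length(i) != 1L)
      stop("need exactly one ", condition, " column per stage (missing/",
           "duplicated: ", st, ")")
    meta$sample_id[i]
  }, "")
  r <- ratios(cgm)[, cols, drop = FALSE]
  complete <- rowSums(is.na(r)) == 0L
  if (any(!complete))
    message(sum(!complete), " CGI(s) not evaluable (missing stage ratio)")
  d <- t(apply(r[complete, , drop = FALSE], 1L, diff))
  colnames(d) <- paste(stageLevels()[-5L], stageLevels()[-1L], sep = "->")
  is_phim <- if (mode == "adjacent") apply(abs(d), 1L, max) > delta
    else apply(r[complete, , drop = FALSE], 1L, function(v)
      max(v) - min(v)) > delta
  group <- rep(NA_integer_, sum(complete))
  if (sum(is_phim) > 0L) {
    if (k > sum(is_phim))
      stop("k = ", k, " exceeds the ", sum(is_phim), " PHIM CGIs")
    km <- .withSeed(seed,
      stats::kmeans(d[is_phim, , drop = FALSE], centers = k,
                    nstart = nstart))
    group[is_phim] <- km$cluster
  }
  out <- data.frame(cgi = rownames(r)[complete], is_phim = is_phim,
                    group = group, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(d), row.names = NULL)
}

#' Highly methylated CGIs per sample
#'
#' Strictly above \code{threshold} (a ratio of exactly 0.25 is not high).
#'
#' @param cgm a \linkS4class{CGIMethylationMatrix}.
#' @param threshold ratio threshold, default 0.25.
#' @return Logical CGI x sample matrix (NA where the ratio is missing).
#' @export
classifyHigh <- function(cgm, threshold = 0.25) {
  ratios(cgm) > threshold
}

#' Aberrantly highly/lowly methylated CGIs versus a reference condition
#'
#' Per (CGI, stage): AHM when the test-condition ratio exceeds the
#' reference-condition ratio by more than \code{delta}, ALM for a decrease
#' by more than \code{delta}, else normal. Swapping test and reference
#' swaps AHM and ALM exactly.
#'
#' @param cgm a \linkS4class{CGIMethylationMatrix} containing both
#'   conditions.
#' @param condition test condition (e.g. "NT" or "SNT").
#' @param reference reference condition, default "NF".
#' @param delta ratio-difference threshold, default 0.25.
#' @param stages stages to compare, default those present in both.
#' @return An \linkS4class{AberrantReport}.
#' @export
detectAberrant <- function(cgm, condition, reference = "NF", delta = 0.25,
                           stages = NULL) {
  meta <- sampleMeta(cgm)
  if (is.null(stages))
    stages <- intersect(stageLevels(),
                        intersect(meta$stage[meta$condition == condition],
                                  meta$stage[meta$condition == reference]))
  if (length(stages) == 0L) stop("no shared stages between conditions")
  r <- ratios(cgm)
  rows <- list()
  for (st in stages) {
    ct <- meta$sample_id[meta$condition == condition & meta$stage == st]
    cr <- meta$sample_id[meta$condition == reference & meta$stage == st]
    if (length(ct) != 1L || length(cr) != 1L)
      stop("need exactly one column per condition at stage ", st)
    ok <- !is.na(r[, ct]) & !is.na(r[, cr])
    diff <- r[ok, ct] - r[ok, cr]
    rows[[st]] <- DataFrame(cgi = rownames(r)[ok], stage = st,
                            ratio_test = unname(r[ok, ct]),
                            ratio_ref = unname(r[ok, cr]),
                            status = ifelse(diff > delta, "AHM",
                                            ifelse(-diff > delta, "ALM",
                                                   "normal")))
  }
  new("AberrantReport", calls = do.call(rbind, rows),
      condition = condition, reference = reference, delta = delta)
}

# AHM CGI ids of a report at one stage
.ahmSet <- function(report, stage) {
  calls <- aberrantCalls(report)
  calls$cgi[calls$stage == stage & calls$status == "AHM"]
}

#' Rescue accounting of NT aberrations in SNT
#'
#' An NT AHM-CGI at a stage is corrected when it is no longer AHM in SNT at
#' the same stage, uncorrected when it remains AHM. The partition is exact:
#' n_corrected + n_uncorrected = n_NT_AHM.
#'
#' @param ntReport,sntReport \linkS4class{AberrantReport}s of NT and SNT
#'   versus the same reference over the same CGI universe.
#' @param stage stage to account.
#' @return list with counts (n_NT_AHM, n_corrected, n_uncorrected,
#'   n_SNT_AHM, n_shared), \code{corrected_fraction}, and the corrected /
#'   uncorrected CGI id vectors.
#' @export
rescueAccounting <- function(ntReport, sntReport, stage) {
  nt <- .ahmSet(ntReport, stage)
  snt <- .ahmSet(sntReport, stage)
  uncorrected <- intersect(nt, snt)
  corrected <- setdiff(nt, snt)
  list(n_NT_AHM = length(nt), n_corrected = length(corrected),
       n_uncorrected = length(uncorrected), n_SNT_AHM = length(snt),
       n_shared = length(uncorrected),
       corrected_fraction = if (length(nt) > 0)
         length(corrected) / length(nt) else NA_real_,
       corrected = corrected, uncorrected = uncorrected)
}

#' Donor origin of aberrant CGIs
#'
#' A stage's AHM CGI is donor-inherited when it is also AHM in the donor
#' cell comparison (cumulus cell CC versus MII oocyte, computed with
#' \code{\link{detectAberrant}}), otherwise de novo. The inherited fraction
#' is reported with a hypergeometric enrichment of the overlap against the
#' CGI universe.
#'
#' @param report \linkS4class{AberrantReport} of a derivation condition.
#' @param donorAhm character vector of donor-vs-oocyte AHM CGI ids.
#' @param stage stage to attribute.
#' @param universe CGI universe ids (e.g. rownames of the matrix both
#'   comparisons were computed on).
#' @return list with \code{origin} (data.frame cgi, origin),
#'   \code{inherited_fraction}, and the enrichment \code{p} and \code{rf}.
#' @export
donorOrigin <- function(report, donorAhm, stage, universe) {
  ahm <- .ahmSet(report, stage)
  donorAhm <- intersect(unique(donorAhm), universe)
  inherited <- intersect(ahm, donorAhm)
  k <- length(inherited)
  enr <- if (length(ahm) > 0L && length(donorAhm) > 0L)
    enrichTest(ahm, donorAhm, universe)
  else list(p = NA_real_, rf = NA_real_)
  list(origin = data.frame(cgi = ahm,
                           origin = ifelse(ahm %in% donorAhm,
                                           "donor_inherited", "de_novo"),
                           stringsAsFactors = FALSE),
       inherited_fraction = if (length(ahm) > 0) k / length(ahm)
         else NA_real_,
       p = enr$p, rf = enr$rf)
}

#' Linear-weighted CpG density around a position
#'
#' CpGs within \code{window/2} of the center contribute weight
#' \code{1 - d / (window/2)} with d their distance; the center CpG itself
#' (d = 0) has weight 1.
#'
#' @param positions CpG positions on one chromosome (0-based).
#' @param center position the density is evaluated at.
#' @param window full window width in bp, default 300.
#' @param weighting \code{"linear"} (default) or \code{"count"} (plain
#'   membership count).
#' @return Numeric density.
#' @export
cpgDensity <- function(positions, center, window = 300L,
                       weighting = c("linear", "count")) {
  weighting <- match.arg(weighting)
  if (window <= 0 || window %% 2 != 0) stop("window must be even, positive")
  half <- window / 2
  d <- abs(positions - center)
  d <- d[d <= half]
  if (weighting == "count") length(d) else sum(1 - d / half)
}

#' Promoter CpG-density classes (HCP / ICP / LCP)
#'
#' Evaluates the linear-weighted CpG density (\code{\link{cpgDensity}}) at
#' each TSS and classifies: HCP when density >= \code{hi}, LCP when
#' density < \code{lo}, else ICP. The thresholds are analysis parameters,
#' not built-in biology.
#'
#' @param tss TSS table (data.frame gene_id, chrom, tss, strand).
#' @param cpgs CpG positions: a GRanges (e.g. \code{rowRanges} of a call
#'   set) or a data.frame with chrom and 0-based pos.
#' @param lo,hi class thresholds.
#' @param window density window, default 300.
#' @return data.frame: gene_id, density, class.
#' @export
classifyPromoters <- function(tss, cpgs, lo, hi, window = 300L) {
  if (lo > hi) stop("need lo <= hi")
  if (is(cpgs, "GRanges")) {
    cpgs <- data.frame(chrom = as.character(seqnames(cpgs)),
                       pos = start(cpgs) - 1L)
  }
  bychrom <- split(cpgs$pos, cpgs$chrom)
  dens <- vapply(seq_len(nrow(tss)), function(i) {
    p <- bychrom[[tss$chrom[i]]]
    if (is.null(p)) 0 else cpgDensity(p, tss$tss[i], window)
  }, 0)
  cls <- ifelse(dens >= hi, "HCP", ifelse(dens < lo, "LCP", "ICP"))
  data.frame(gene_id = tss$gene_id, density = dens, class = cls,
             stringsAsFactors = FALSE)
}

#' Associate each CGI with its closest gene within a distance cutoff
#'
#' Distance is measured from the CGI interval boundary (0 for a TSS inside
#' the island); among genes whose TSS lies within \code{maxDist}, the
#' minimum-distance gene is chosen, ties broken by lexicographic gene id
#' (reported with a message).
#'
#' @param cgis named GRanges of CGI intervals.
#' @param tss TSS table (data.frame gene_id, chrom, tss, strand; tss
#'   0-based).
#' @param maxDist distance cutoff in bp, default 5000.
#' @return data.frame: cgi, gene_id, distance — one row per associated CGI.
#' @export
associateCgiGene <- function(cgis, tss, maxDist = 5000L) {
  if (is.null(names(cgis))) names(cgis) <- paste0("CGI_", seq_along(cgis))
  out <- vector("list", length(cgis))
  ties <- 0L
  chroms <- as.character(seqnames(cgis))
  s0 <- start(cgis) - 1L; e0 <- end(cgis)   # 0-based half-open
  for (i in seq_along(cgis)) {
    cand <- tss[tss$chrom == chroms[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    p <- cand$tss
    d <- ifelse(p < s0[i], s0[i] - p, ifelse(p >= e0[i], p - e0[i] + 1L, 0L))
    ok <- d <= maxDist
    if (!any(ok)) next
    dmin <- min(d[ok])
    hit <- cand$gene_id[ok][d[ok] == dmin]
    if (length(hit) > 1L) ties <- ties + 1L
    out[[i]] <- data.frame(cgi = names(cgis)[i],
                           gene_id = sort(hit)[1L], distance = dmin,
                           stringsAsFactors = FALSE)
  }
  if (ties > 0L)
    message(ties, " CGI(s) had distance ties; lexicographically first ",
            "gene kept")
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cgi = character(0), gene_id = character(0),
                      distance = integer(0))
  rownames(res) <- NULL
  res
}
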