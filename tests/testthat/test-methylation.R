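test_that("coverage filter requires every replicate and pools counts", {
  r1 <- toyCalls(c(100L, 200L, 300L), c(1L, 2L, 3L), c(4L, 5L, 9L),
                 sample_id = "r1", condition = "NF", stage = "TE3.5",
                 replicate = 1L)
  r2 <- toyCalls(c(100L, 200L, 300L), c(2L, 3L, 1L), c(10L, 7L, 4L),
                 sample_id = "r2", condition = "NF", stage = "TE3.5",
                 replicate = 2L)
  mcs <- combineCallSets(r1, r2)
  pooled <- retainCpgs(mcs, minCov = 5)
  expect_equal(colnames(pooled), "NF_TE3.5")
  t <- SummarizedExperiment::assay(pooled, "total")[, 1]
  m <- SummarizedExperiment::assay(pooled, "meth")[, 1]
  expect_true(is.na(t[1]))           # coverage 4 in one replicate: dropped
  expect_equal(t[2], 12L)            # coverages (5, 7) pooled
  expect_equal(m[2], 5L)
  expect_true(is.na(t[3]))           # coverage 4 in the other replicate
  # any-replicate mode keeps the qualifying replicate only
  any <- retainCpgs(mcs, minCov = 5, mode = "any")
  expect_equal(SummarizedExperiment::assay(any, "total")[, 1],
               c(10L, 12L, 9L))
  # monotone: raising min_cov never adds a CpG
  stricter <- retainCpgs(mcs, minCov = 8)
  det5 <- !is.na(SummarizedExperiment::assay(pooled, "total"))
  det8 <- !is.na(SummarizedExperiment::assay(stricter, "total"))
  expect_true(all(det8 <= det5))
})

test_that("CGI methylation is the mean of CpG ratios, not the pooled ratio", {
  # ratios (0.2, 0.4, 0.6) with unequal coverage: mean 0.4, pooled != 0.4
  calls <- toyCalls(c(100L, 120L, 140L, 1000L),
                    meth = c(2L, 2L, 30L, 1L),
                    total = c(10L, 5L, 50L, 10L),
                    sample_id = "NF_TE3.5", condition = "NF",
                    stage = "TE3.5")
  cgi <- GenomicRanges::GRanges("chr1", IRanges::IRanges(91, 200))
  names(cgi) <- "CGI_A"
  cgm <- cgiMethylation(calls, cgi, minDetected = 3)
  expect_equal(unname(ratios(cgm)["CGI_A", 1]), mean(c(0.2, 0.4, 0.6)))
  expect_equal(unname(SummarizedExperiment::assay(cgm, "pooledMeth")[1, 1]), 34L)
  expect_equal(unname(SummarizedExperiment::assay(cgm, "pooledTotal")[1, 1]), 65L)
  expect_false(34 / 65 == 0.4)       # constructed so pooling would differ
  # the CpG outside the island does not contribute
  expect_equal(unname(SummarizedExperiment::assay(cgm, "detectedCpgs")[1, 1]), 3L)
})

test_that("CGI retention needs the detected-CpG minimum in every sample", {
  pos <- c(100L, 120L, 140L, 160L, 180L)
  a <- toyCalls(pos, rep(1L, 5), rep(10L, 5), sample_id = "NF_TE3.5",
                condition = "NF", stage = "TE3.5")
  bMeth <- matrix(c(1L, 1L, 1L, 1L, NA), ncol = 1)
  bTot <- matrix(c(10L, 10L, 10L, 10L, NA), ncol = 1)
  b <- MethylationCallSet(rep("chr1", 5), pos, bMeth, bTot,
                          toyMeta("NF_TE4.5", "NF", "TE4.5"))
  mcs <- combineCallSets(a, b)
  dropped <- cgiMethylation(mcs, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(91, 200)), minDetected = 5)
  expect_equal(nrow(dropped), 0L)    # 4 detected CpGs in one sample
  kept <- cgiMethylation(mcs, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(91, 200)), minDetected = 5, mode = "any")
  expect_equal(nrow(kept), 1L)
})

test_that("differential CGIs need both the delta and the Fisher p", {
  meta <- toyMeta(c("A", "B"))
  spread <- function(total, ncp) {  # exact integer split across CpGs
    base <- total %/% ncp
    base + (seq_len(ncp) <= total %% ncp)
  }
  mk <- function(mA, tA, mB, tB, ncp = 5) {
    pos <- seq(100L, by = 20L, length.out = ncp)
    meth <- cbind(spread(mA, ncp), spread(mB, ncp))
    tot <- cbind(spread(tA, ncp), spread(tB, ncp))
    mcs <- MethylationCallSet(rep("chr1", ncp), pos, meth, tot, meta)
    cgiMethylation(mcs, GenomicRanges::GRanges("chr1",
                                               IRanges::IRanges(91, 300)),
                   minDetected = 3)
  }
  # A = 30/40 vs B = 2/40: delta 0.7, strongly significant
  cgm <- mk(30, 40, 2, 40)
  res <- differentialCgis(cgm, "A", "B")
  expect_true(res$called)
  expect_equal(res$pvalue, oracleFisher(30, 10, 2, 38), tolerance = 1e-10)
  # identical counts: p = 1, delta 0, not called
  same <- differentialCgis(mk(10, 40, 10, 40), "A", "B")
  expect_false(same$called)
  expect_equal(same$pvalue, 1)
  # large delta but 3 reads per sample: underpowered, not called
  weak <- mk(2, 3, 0, 3, ncp = 3)
  reswk <- differentialCgis(weak, "A", "B")
  expect_equal(reswk$pvalue, oracleFisher(2, 1, 0, 3), tolerance = 1e-10)
  expect_false(reswk$called)
})

test_that("implementation Fisher p matches enumeration for pooled totals <= 60", {
  set.seed(33)
  for (i in 1:25) {
    tA <- sample(3:30, 1); tB <- sample(3:30, 1)
    mA <- sample(0:tA, 1); mB <- sample(0:tB, 1)
    p_impl <- stats::fisher.test(matrix(c(mA, tA - mA, mB, tB - mB), 2))$p.value
    expect_equal(p_impl, oracleFisher(mA, tA - mA, mB, tB - mB),
                 tolerance = 1e-10)
  }
})

test_that("PHIM detection applies the adjacent-delta rule and recovers groups", {
  stages <- stageLevels()
  meta <- toyMeta(paste0("NF_", stages), "NF", stages, replicate = 1L)
  ratio <- rbind(flat = rep(0.05, 5),
                 jump = c(0.05, 0.05, 0.6, 0.6, 0.6),
                 creep = c(0.05, 0.25, 0.45, 0.6, 0.65),
                 high_flat = rep(0.8, 5))
  cgm <- cgiMatrixFromRatios(ratio, meta)
  ph <- detectPhim(cgm, "NF", k = 1, seed = 1)
  expect_equal(ph$is_phim, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(unname(as.matrix(ph[2, 4:7])),
               matrix(c(0, 0.55, 0, 0), 1), tolerance = 1e-12)
  # global mode also catches the creeping island (max - min = 0.6)
  phg <- detectPhim(cgm, "NF", k = 1, seed = 1, mode = "global")
  expect_true(phg$is_phim[3])
  expect_error(detectPhim(cgm, "NF", k = 5, seed = 1), "exceeds")
})

test_that("noise-free PHIM calling separates 0.3 from 0.2 jumps exactly", {
  stages <- stageLevels()
  meta <- toyMeta(paste0("NF_", stages), "NF", stages, replicate = 1L)
  jump <- function(size) c(0.05, 0.05, 0.05 + size, 0.05 + size, 0.05 + size)
  ratio <- rbind(matrix(rep(jump(0.30), each = 20), 20),
                 matrix(rep(jump(0.20), each = 20), 20))
  rownames(ratio) <- sprintf("c%02d", 1:40)
  ph <- detectPhim(cgiMatrixFromRatios(ratio, meta), "NF", k = 1, seed = 1)
  expect_true(all(ph$is_phim[1:20]))     # sensitivity 1 at jump 0.30
  expect_false(any(ph$is_phim[21:40]))   # specificity 1 at jump 0.20
})

test_that("highly methylated classification is strict at 0.25", {
  meta <- toyMeta("s1")
  r <- matrix(c(0.25, 0.26, 0.1, NA), 4, 1,
              dimnames = list(paste0("c", 1:4), "s1"))
  hi <- classifyHigh(cgiMatrixFromRatios(r, meta))
  expect_identical(unname(hi[, 1]), c(FALSE, TRUE, FALSE, NA))
})

test_that("aberrant calling is a thresholded difference with exact mirror", {
  stages <- c("TE3.5", "TE4.5")
  meta <- toyMeta(c("NF_TE3.5", "NF_TE4.5", "NT_TE3.5", "NT_TE4.5"),
                  c("NF", "NF", "NT", "NT"), rep(stages, 2), replicate = 1L)
  ratio <- cbind("NF_TE3.5" = c(0.10, 0.70, 0.30),
                 "NF_TE4.5" = c(0.10, 0.10, 0.30),
                 "NT_TE3.5" = c(0.70, 0.10, 0.31),
                 "NT_TE4.5" = c(0.10, 0.12, 0.30))
  rownames(ratio) <- c("a", "b", "c")
  cgm <- cgiMatrixFromRatios(ratio, meta)
  rep1 <- detectAberrant(cgm, "NT", "NF")
  calls <- aberrantCalls(rep1)
  get <- function(cg, st) calls$status[calls$cgi == cg & calls$stage == st]
  expect_equal(get("a", "TE3.5"), "AHM")   # 0.70 vs 0.10
  expect_equal(get("b", "TE3.5"), "ALM")   # 0.10 vs 0.70
  expect_equal(get("c", "TE3.5"), "normal")  # 0.01 difference
  expect_equal(get("b", "TE4.5"), "normal")
  # swapping test and reference swaps AHM and ALM exactly
  rep2 <- detectAberrant(cgm, "NF", "NT")
  c2 <- aberrantCalls(rep2)
  map <- c(AHM = "ALM", ALM = "AHM", normal = "normal")
  expect_identical(unname(map[calls$status]), c2$status)
})

test_that("rescue accounting partitions the NT AHM set exactly", {
  stages <- "TE3.5"
  meta <- toyMeta(c("NF_TE3.5", "NT_TE3.5", "SNT_TE3.5"),
                  c("NF", "NT", "SNT"), stages, replicate = 1L)
  n <- 30
  nf <- rep(0.05, n)
  nt <- c(rep(0.7, 20), rep(0.05, 10))          # 20 NT AHM
  snt <- c(rep(0.7, 6), rep(0.05, 24))          # 6 remain AHM in SNT
  ratio <- cbind("NF_TE3.5" = nf, "NT_TE3.5" = nt, "SNT_TE3.5" = snt)
  rownames(ratio) <- sprintf("c%02d", 1:n)
  cgm <- cgiMatrixFromRatios(ratio, meta)
  ntR <- detectAberrant(cgm, "NT", "NF")
  sntR <- detectAberrant(cgm, "SNT", "NF")
  ra <- rescueAccounting(ntR, sntR, "TE3.5")
  expect_equal(ra$n_NT_AHM, 20L)
  expect_equal(ra$n_corrected, 14L)
  expect_equal(ra$n_uncorrected, 6L)
  expect_equal(ra$n_corrected + ra$n_uncorrected, ra$n_NT_AHM)
  expect_equal(ra$n_SNT_AHM, 6L)
  # SNT free of AHM: everything corrected; identical reports: none corrected
  raAll <- rescueAccounting(ntR, detectAberrant(cgm, "NF", "NF"), "TE3.5")
  expect_equal(raAll$n_corrected, 20L)
  raNone <- rescueAccounting(ntR, ntR, "TE3.5")
  expect_equal(raNone$n_corrected, 0L)
})

test_that("donor origin splits AHM into inherited and de novo", {
  ahmR <- local({
    meta <- toyMeta(c("NF_TE3.5", "NT_TE3.5"), c("NF", "NT"), "TE3.5",
                    replicate = 1L)
    ratio <- cbind("NF_TE3.5" = rep(0.05, 10),
                   "NT_TE3.5" = c(rep(0.7, 6), rep(0.05, 4)))
    rownames(ratio) <- paste0("c", 1:10)
    detectAberrant(cgiMatrixFromRatios(ratio, meta), "NT", "NF")
  })
  universe <- paste0("c", 1:10)
  res <- donorOrigin(ahmR, donorAhm = c("c1", "c2", "c3", "c9"),
                     stage = "TE3.5", universe = universe)
  expect_equal(res$inherited_fraction, 0.5)    # c1-c3 of the 6 AHM
  expect_equal(sum(res$origin$origin == "donor_inherited"), 3L)
  # empty donor set: everything de novo
  res0 <- donorOrigin(ahmR, donorAhm = character(0), stage = "TE3.5",
                      universe = universe)
  expect_equal(sum(res0$origin$origin == "de_novo"), 6L)
  # AHM subset of donor set: fraction 1
  res1 <- donorOrigin(ahmR, donorAhm = paste0("c", 1:7), stage = "TE3.5",
                      universe = universe)
  expect_equal(res1$inherited_fraction, 1)
})

test_that("linear CpG density weights distances as specified", {
  expect_equal(cpgDensity(integer(0), 500), 0)
  expect_equal(cpgDensity(500L, 500L), 1)
  # distances 0, 75, 150 in a 300-bp window: weights 1, 0.5, 0
  expect_equal(cpgDensity(c(500L, 575L, 650L), 500L, window = 300), 1.5)
  # membership agrees with the plain-count oracle
  pos <- c(300L, 360L, 420L, 500L, 640L, 651L, 900L)
  expect_equal(cpgDensity(pos, 500L, weighting = "count"),
               sum(abs(pos - 500L) <= 150L))
  expect_error(cpgDensity(1L, 1L, window = 301), "even")
})

test_that("promoter classes follow the configured density thresholds", {
  tss <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                    tss = c(1000L, 5000L, 9000L), strand = "+")
  cpgs <- data.frame(chrom = "chr1",
                     pos = c(1000L, 1020L, 1040L, 1060L, 5000L, 5100L))
  pc <- classifyPromoters(tss, cpgs, lo = 1.0, hi = 2.5)
  expect_equal(pc$class, c("HCP", "ICP", "LCP"))
  expect_equal(pc$density[3], 0)
  # direct threshold rule on known densities
  d <- c(0.1, 0.5, 0.9)
  expect_equal(ifelse(d >= 0.7, "HCP", ifelse(d < 0.3, "LCP", "ICP")),
               c("LCP", "ICP", "HCP"))
})

test_that("CGI-gene association picks the closest TSS within 5 kb", {
  cgis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 10600))
  names(cgis) <- "CGI_1"
  tssOf <- function(pos) data.frame(gene_id = paste0("g", seq_along(pos)),
                                    chrom = "chr1", tss = pos, strand = "+")
  # TSS inside: distance 0
  inside <- associateCgiGene(cgis, tssOf(10300L))
  expect_equal(inside$distance, 0L)
  # boundary: 5001 bp away is not associated (island ends at 0-based 10600)
  expect_equal(nrow(associateCgiGene(cgis, tssOf(15600L))), 0L)
  expect_equal(associateCgiGene(cgis, tssOf(15599L))$distance, 5000L)
  # nearer gene wins
  near <- associateCgiGene(cgis, tssOf(c(10700L, 14000L)))
  expect_equal(near$gene_id, "g1")
  expect_equal(near$distance, 101L)
})
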