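test_that("RPM normalization matches hand-computed values", {
  cnt <- matrix(c(0L, 1L, 999999L, 100L, 0L, 1999900L), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  nm <- normalizeRpm(cnt)
  expect_equal(nm["g1", "s1"], 0)                       # count 0 -> 0
  expect_equal(nm["g2", "s1"], 1)                       # 1 read in 1e6 -> log2(2)
  expect_equal(nm["g1", "s2"], log2(100 / 2e6 * 1e6 + 1))  # log2(51) ~ 5.672
  expect_equal(nm["g1", "s2"], 5.6724253, tolerance = 1e-7)
  # per-sample RPM sums are exactly 1e6
  rpm <- (2^nm - 1)
  expect_equal(unname(colSums(rpm)), c(1e6, 1e6))
  # monotone in counts within a sample
  expect_true(all(diff(nm[order(cnt[, 1]), 1]) >= 0))
  expect_error(normalizeRpm(matrix(0L, 2, 1)), "zero library")
})

test_that("expressed-gene filter is strict at the boundary", {
  nm <- rbind(all0 = c(0, 0), exact1 = c(1, 1), above = c(0.2, 1.01),
              below = c(0.99, 0.5))
  colnames(nm) <- c("a", "b")
  expect_equal(filterExpressed(nm), "above")
})

test_that("PCA agrees with a brute-force eigendecomposition oracle", {
  set.seed(42)
  norm <- matrix(rnorm(8 * 6), 8, 6,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:6)))
  pca <- pcaScoresLoadings(norm, nComponents = 3)
  # oracle: eigenvectors of the gene-gene covariance across samples
  X <- t(norm - rowMeans(norm))
  ev <- eigen(crossprod(X) / 1)            # X'X shares eigenvectors with cov
  for (j in 1:3) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(pca$loadings[, j]), v, tolerance = 1e-8)
  }
  # scores reproduce projections of the centered data
  expect_equal(unname(pca$scores[, 1]), unname(X %*% pca$loadings[, 1])[, 1],
               tolerance = 1e-8)
  # 1-D data: PC1 explains everything
  line <- outer(c(1, 2, 3, 4), c(0, 1, 2, 5, 9))
  rownames(line) <- paste0("g", 1:4); colnames(line) <- paste0("s", 1:5)
  p1 <- pcaScoresLoadings(line, nComponents = 2)
  expect_equal(p1$explainedVariance[1], 1)
  # identical samples: zero scores, degenerate but no error
  same <- matrix(5, 3, 2, dimnames = list(paste0("g", 1:3), c("a", "b")))
  p0 <- pcaScoresLoadings(same, nComponents = 1)
  expect_equal(unname(p0$scores[, 1]), c(0, 0))
  expect_error(pcaScoresLoadings(norm, nComponents = 10), "components")
})

test_that("top-loading selection counts and ties behave as specified", {
  set.seed(7)
  L <- matrix(runif(100), 100, 1, dimnames = list(sprintf("g%03d", 1:100), "PC1"))
  expect_length(selectTopLoadingGenes(L, 0.05, components = 1), 5L)
  # total tie returns everything
  L2 <- matrix(0.5, 40, 1, dimnames = list(paste0("g", 1:40), "PC1"))
  expect_length(selectTopLoadingGenes(L2, 0.05, components = 1), 40L)
  expect_error(selectTopLoadingGenes(L, 0), "fraction")
  expect_error(selectTopLoadingGenes(L, 0.05, components = 3), "component")
})

test_that("trend clustering groups duplicates and labels monotone centroids", {
  stages <- stageLevels()
  meta <- toyMeta(paste0("s", 1:5), "NF", stages, replicate = 1L)
  up <- c(0, 2, 4, 6, 8); down <- rev(up)
  cnt <- rbind(matrix(rep(2^up * 50, each = 4), 4, byrow = FALSE),
               matrix(rep(2^down * 50, each = 4), 4, byrow = FALSE))
  cnt <- matrix(as.integer(round(cnt)), 8, 5,
                dimnames = list(paste0("g", 1:8), meta$sample_id))
  em <- normalizeRpm(ExpressionMatrix(cnt, meta))
  cl <- clusterTrendGenes(em, rownames(cnt), k = 2)
  expect_equal(length(unique(cl$assignment$cluster[1:4])), 1L)
  expect_equal(length(unique(cl$assignment$cluster[5:8])), 1L)
  trends <- cl$assignment$trend
  expect_setequal(unique(trends[1:4]), "Pro")
  expect_setequal(unique(trends[5:8]), "Down")
  expect_error(clusterTrendGenes(em, rownames(cnt), k = 20), "k exceeds")
})

test_that("planted six-cluster structure is recovered with high ARI", {
  cfg <- simConfig(seed = 12)
  ex <- simulateExpression(cfg)
  em <- normalizeRpm(ex$expr)
  meta <- sampleMeta(em)
  nf <- meta$sample_id[meta$condition == "NF"]
  pca <- pcaScoresLoadings(normValues(em)[filterExpressed(em), nf],
                           nComponents = 2)
  sel <- selectTopLoadingGenes(pca$loadings, 0.05)
  # driver TFs dominate the loadings
  expect_gte(mean(ex$panel %in% sel), 0.9)
  tr <- ex$truth
  genes <- intersect(sel, tr$gene_id[!is.na(tr$cluster)])
  cl <- clusterTrendGenes(em, genes, k = 6)
  expect_gte(adjustedRandIndex(cl$assignment$cluster,
                               tr$cluster[match(genes, tr$gene_id)]), 0.9)
  # Pro-cluster genes labeled Pro, down cluster labeled Down
  byTruth <- split(cl$assignment$trend, tr$cluster[match(genes, tr$gene_id)])
  expect_true(mean(unlist(byTruth[c("1", "2", "3")]) == "Pro") > 0.9)
  expect_true(mean(byTruth[["4"]] == "Down") > 0.9)
})

test_that("DEG thresholds and direction labels behave as specified", {
  # identical groups: no calls
  cnt <- matrix(rep(c(10L, 200L, 3000L), 4), 3, 4,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  em <- normalizeRpm(toyExpr(cnt))
  deg <- callDegs(em, groupA = c("s1", "s2"), groupB = c("s3", "s4"))
  expect_false(any(deg$significant))
  expect_true(all(deg$pvalue == 1))
  # supplied statistic table: exactly the qualifying genes survive
  tab <- data.frame(gene_id = paste0("g", 1:6),
                    pvalue = c(1e-5, 1e-4, 0.5, 1e-6, 0.2, 1e-9),
                    lfc = c(3, -2.5, 4, 1.9, -3, 2.1),
                    padj = c(0.001, 0.005, 0.6, 0.002, 0.3, 1e-7))
  deg2 <- callDegs(stats = tab, pThresh = 0.01, lfcThresh = 2)
  expect_equal(deg2$gene_id[deg2$significant], c("g1", "g2", "g6"))
  expect_equal(deg2$direction, c("up", "down", "up", "up", "down", "up"))
  # fewer than 2 replicates: actionable error
  expect_error(callDegs(em, groupA = "s1", groupB = c("s3", "s4")),
               "external")
})

test_that("DEG direction labels are antisymmetric under group swap", {
  cfg <- simConfig(seed = 21, n_genes = 200, n_tf = 60, n_driver_tf = 20)
  ex <- simulateExpression(cfg)
  em <- normalizeRpm(ex$expr)
  meta <- sampleMeta(em)
  a <- meta$sample_id[meta$condition == "NT" & meta$stage == "outgrowth"]
  b <- meta$sample_id[meta$condition == "NF" & meta$stage == "outgrowth"]
  d1 <- callDegs(em, a, b)
  d2 <- callDegs(em, b, a)
  expect_equal(d1$lfc, -d2$lfc)
  expect_equal(d1$pvalue, d2$pvalue)
  expect_identical(d1$significant, d2$significant)
  sig <- d1$significant
  expect_true(all(d1$direction[sig] != d2$direction[sig]))
})

test_that("a planted 8-fold up-shift at low dispersion is called up", {
  set.seed(91)
  nrep <- 5L
  mu <- c(target = 4000, flat1 = 300, flat2 = 1500, flat3 = 50,
          flat4 = 60000)  # dominant stable gene keeps library sizes comparable
  mkGroup <- function(shift) {
    sapply(seq_len(nrep), function(i) {
      m <- mu; m["target"] <- m["target"] * shift
      as.integer(rnbinom(length(m), mu = m, size = 100))
    })
  }
  cnt <- cbind(mkGroup(1), mkGroup(1 / 8))
  dimnames(cnt) <- list(names(mu), paste0("s", 1:10))
  em <- normalizeRpm(toyExpr(cnt))
  deg <- callDegs(em, groupA = paste0("s", 1:5), groupB = paste0("s", 6:10),
                  pThresh = 0.01, lfcThresh = 2)
  tgt <- deg[deg$gene_id == "target", ]
  expect_true(tgt$significant)
  expect_equal(tgt$direction, "up")
  expect_false(any(deg$significant[deg$gene_id != "target"]))
})
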