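# run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Simulation configuration for the TSC derivation generator
#'
#' Defines the planted structure of synthetic expression and methylome
#' datasets: a five-stage derivation (see \code{\link{stageLevels}}) under
#' NF, NT and SNT, six expression trend clusters with a driver-TF panel,
#' and CpG-island methylation with progressive (PHIM) jumps, donor-inherited
#' and de novo aberrations, Scriptaid rescue, and FGF4-stage effects.
#'
#' Expression counts are negative binomial around stage/condition means on
#' the log2(RPM+1) scale; \code{noise_sd} adds log2-scale multiplicative
#' jitter to the per-replicate mean. Methylation counts are binomial with
#' per-CpG coverage 1 + Poisson(\code{coverage_mean} - 1) and a detection
#' dropout.
#'
#' @param seed integer RNG seed.
#' @param n_genes,n_tf,n_driver_tf gene universe, TF universe and driver
#'   panel sizes (\code{n_driver_tf <= n_tf <= n_genes}).
#' @param replicates RNA replicates per stage per condition (2-5).
#' @param library_size expected library size used to convert RPM to counts.
#' @param nb_dispersion NB dispersion (mean-dispersion parameterization;
#'   0 switches to deterministic rounded means).
#' @param noise_sd SD of log2-scale replicate jitter (normalized units).
#' @param nt_down_factor multiplier (< 1) applied to cluster-2/3 driver-TF
#'   means at NT outgrowth.
#' @param rescue_fraction fraction of NT-perturbed drivers / aberrant CGIs
#'   restored in SNT.
#' @param pro_fractions,down_fraction,transient_fractions planted non-TF
#'   gene fractions for clusters 1-3, 4, and 5-6.
#' @param tf_cluster456 TF counts planted in clusters 4-6 (non-driver
#'   dynamic TFs).
#' @param n_cgis CGI count; \code{cpgs_per_cgi} an inclusive integer range.
#' @param coverage_mean mean per-CpG coverage; \code{dropout} probability a
#'   CpG goes undetected in a column.
#' @param meth_replicates RRBS replicates per biological sample.
#' @param phim_fractions length-5 planted PHIM group fractions of
#'   \code{n_cgis}.
#' @param donor_ahm,denovo_ahm,fgf4_ahm planted aberrant-CGI fractions:
#'   donor-inherited (high in the cumulus-cell profile), de novo (high only
#'   in NT/SNT derivation), and FGF4-stage (high only at TSC_P1/TSC_Pn in
#'   NT and SNT).
#' @param p_low,p_high background and methylated beta-values of planted
#'   CGIs.
#' @return A validated list of class \code{tscdyn_config}.
#' @export
#' @examples
#' cfg <- simConfig(seed = 7, n_genes = 300, n_tf = 60, n_driver_tf = 20)
#' str(cfg[c("n_genes", "n_tf", "n_driver_tf")])
simConfig <- function(seed = 1L,
                      n_genes = 2000L, n_tf = 300L, n_driver_tf = 75L,
                      replicates = 3L, library_size = 2e6,
                      nb_dispersion = 0.05, noise_sd = 0.2,
                      nt_down_factor = 0.25, rescue_fraction = 0.8,
                      pro_fractions = c(0.012, 0.018, 0.018),
                      down_fraction = 0.025,
                      transient_fractions = c(0.018, 0.018),
                      tf_cluster456 = c(11L, 10L, 10L),
                      n_cgis = 600L, cpgs_per_cgi = c(8L, 20L),
                      coverage_mean = 30, dropout = 0.05,
                      meth_replicates = 2L,
                      phim_fractions = rep(0.03, 5),
                      donor_ahm = 0.10, denovo_ahm = 0.0667,
                      fgf4_ahm = 0.05,
                      p_low = 0.05, p_high = 0.6) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_tf = as.integer(n_tf), n_driver_tf = as.integer(n_driver_tf),
              replicates = as.integer(replicates),
              library_size = library_size, nb_dispersion = nb_dispersion,
              noise_sd = noise_sd, nt_down_factor = nt_down_factor,
              rescue_fraction = rescue_fraction,
              pro_fractions = pro_fractions, down_fraction = down_fraction,
              transient_fractions = transient_fractions,
              tf_cluster456 = as.integer(tf_cluster456),
              n_cgis = as.integer(n_cgis),
              cpgs_per_cgi = as.integer(cpgs_per_cgi),
              coverage_mean = coverage_mean, dropout = dropout,
              meth_replicates = as.integer(meth_replicates),
              phim_fractions = phim_fractions, donor_ahm = donor_ahm,
              denovo_ahm = denovo_ahm, fgf4_ahm = fgf4_ahm,
              p_low = p_low, p_high = p_high)
  fr <- c(cfg$pro_fractions, cfg$down_fraction, cfg$transient_fractions,
          cfg$phim_fractions, cfg$donor_ahm, cfg$denovo_ahm, cfg$fgf4_ahm,
          cfg$rescue_fraction, cfg$dropout)
  if (any(fr < 0 | fr > 1)) stop("planted fractions must lie in [0, 1]")
  if (!(cfg$n_driver_tf <= cfg$n_tf && cfg$n_tf <= cfg$n_genes))
    stop("need n_driver_tf <= n_tf <= n_genes")
  if (cfg$replicates < 2L || cfg$replicates > 5L)
    stop("replicates must be in [2, 5]")
  if (cfg$nb_dispersion < 0 || cfg$noise_sd < 0 || cfg$coverage_mean <= 0)
    stop("nb_dispersion and noise_sd must be >= 0, coverage_mean > 0")
  if (cfg$nt_down_factor <= 0 || cfg$nt_down_factor >= 1)
    stop("nt_down_factor must lie in (0, 1)")
  if (length(cfg$cpgs_per_cgi) != 2L || cfg$cpgs_per_cgi[1L] < 1L ||
      diff(cfg$cpgs_per_cgi) < 0L)
    stop("cpgs_per_cgi must be an increasing positive range")
  if (sum(cfg$phim_fractions, cfg$donor_ahm, cfg$denovo_ahm, cfg$fgf4_ahm) > 1)
    stop("planted CGI fractions exceed 1")
  if (sum(cfg$pro_fractions, cfg$down_fraction, cfg$transient_fractions) > 1)
    stop("planted gene-cluster fractions exceed 1")
  structure(cfg, class = "tscdyn_config")
}

# mean log2(RPM+1) stage profiles of the six trend clusters; rows = clusters
.clusterProfiles <- function() {
  rbind(c1 = c(2.0, 4.5, 6.0, 7.2, 8.0),   # rising from TE4.5, saturating
        c2 = c(2.0, 2.0, 4.5, 6.5, 8.0),   # rising from outgrowth
        c3 = c(2.0, 2.0, 3.0, 5.5, 8.5),   # shallow outgrowth rise, steep late
        c4 = c(8.0, 8.0, 6.0, 4.0, 2.0),   # falling from outgrowth
        c5 = c(7.0, 4.0, 2.0, 4.0, 7.0),   # V
        c6 = c(2.0, 5.0, 7.0, 5.0, 2.0))   # inverted V
}

#' Simulate a TSC-derivation expression time course
#'
#' Plants six trend clusters (1-3 continuously upregulated "Pro", 4
#' downregulated, 5/6 transient), a driver-TF panel inside clusters 1-3,
#' an NT-specific down-shift of cluster-2/3 drivers at outgrowth, and SNT
#' rescue of a configured fraction of them. Counts are NB around the
#' planted means (see \code{\link{simConfig}}).
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{expr} (an \linkS4class{ExpressionMatrix}),
#'   \code{truth} (data.frame: gene_id, cluster, is_tf, is_driver,
#'   nt_perturbed, rescued), \code{panel} (driver TF ids) and
#'   \code{tf_universe} (all TF ids).
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "tscdyn_config"))
  .withSeed(config$seed, .simulateExpressionImpl(config))
}

.simulateExpressionImpl <- function(cfg) {
  stages <- stageLevels()
  prof <- .clusterProfiles()
  ntf <- cfg$n_tf
  tf_ids <- sprintf("tf_%04d", seq_len(ntf))
  other_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes - ntf))
  ids <- c(tf_ids, other_ids)

  cluster <- rep(NA_integer_, cfg$n_genes)
  names(cluster) <- ids
  # driver TFs: clusters 1-3 at 20/40/40
  n1 <- round(0.2 * cfg$n_driver_tf)
  n2 <- round(0.4 * cfg$n_driver_tf)
  n3 <- cfg$n_driver_tf - n1 - n2
  drivers <- tf_ids[seq_len(cfg$n_driver_tf)]
  cluster[drivers] <- rep(1:3, c(n1, n2, n3))
  # non-driver dynamic TFs in clusters 4-6 (scaled down in small universes)
  k456 <- cfg$tf_cluster456
  avail <- max(0L, ntf - cfg$n_driver_tf)
  if (sum(k456) > avail)
    k456 <- as.integer(floor(k456 * avail / sum(k456)))
  dyn456 <- tf_ids[cfg$n_driver_tf + seq_len(sum(k456))]
  cluster[dyn456] <- rep(4:6, k456)
  # non-TF planted genes
  ngo <- length(other_ids)
  kgene <- round(c(cfg$pro_fractions, cfg$down_fraction,
                   cfg$transient_fractions) * cfg$n_genes)
  kgene <- pmin(kgene, ngo)  # guard tiny universes
  if (sum(kgene) > ngo) kgene <- floor(kgene * ngo / sum(kgene))
  planted <- other_ids[seq_len(sum(kgene))]
  cluster[planted] <- rep(1:6, kgene)

  # per-gene mean profile on the log2(RPM+1) scale; driver TFs carry the
  # full planted amplitude, other dynamic genes follow attenuated (targets
  # downstream of the drivers), so drivers dominate the PC loadings
  amp <- stats::runif(cfg$n_genes, 0.85, 1.15)
  follower <- !is.na(cluster) & !(ids %in% drivers)
  amp[follower] <- stats::runif(sum(follower), 0.3, 0.6)
  offs <- stats::rnorm(cfg$n_genes, 0, 0.3)
  flat_level <- stats::runif(cfg$n_genes, 0.5, 7)
  mu_log <- matrix(0, cfg$n_genes, 5L, dimnames = list(ids, stages))
  for (g in seq_len(cfg$n_genes)) {
    mu_log[g, ] <- if (is.na(cluster[g])) rep(flat_level[g], 5L)
      else pmax(0, prof[cluster[g], ] * amp[g] + offs[g])
  }

  # NT down-shift of cluster-2/3 drivers at outgrowth, on the RPM scale
  perturbed <- drivers[cluster[drivers] %in% c(2L, 3L)]
  n_resc <- round(cfg$rescue_fraction * length(perturbed))
  rescued <- sort(sample(perturbed, n_resc))
  shift_log <- function(x) log2(pmax(0, (2^x - 1) * cfg$nt_down_factor) + 1)

  conds <- c("NF", "NT", "SNT")
  meta <- expand.grid(replicate = seq_len(cfg$replicates), stage = stages,
                      condition = conds, stringsAsFactors = FALSE)
  meta <- meta[, c("condition", "stage", "replicate")]
  meta$sample_id <- sprintf("%s_%s_r%d", meta$condition, meta$stage,
                            meta$replicate)
  counts <- matrix(0L, cfg$n_genes, nrow(meta), dimnames = list(ids, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    mu <- mu_log[, meta$stage[j]]
    if (meta$condition[j] == "NT" && meta$stage[j] == "outgrowth")
      mu[perturbed] <- shift_log(mu[perturbed])
    if (meta$condition[j] == "SNT" && meta$stage[j] == "outgrowth") {
      unresc <- setdiff(perturbed, rescued)
      mu[unresc] <- shift_log(mu[unresc])
    }
    rpm <- pmax(0, 2^(mu + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)) - 1)
    lam <- rpm / 1e6 * cfg$library_size
    counts[, j] <- if (cfg$nb_dispersion > 0)
      stats::rnbinom(cfg$n_genes, mu = lam, size = 1 / cfg$nb_dispersion)
    else as.integer(round(lam))
  }

  truth <- data.frame(gene_id = ids, cluster = unname(cluster),
                      is_tf = ids %in% tf_ids,
                      is_driver = ids %in% drivers,
                      nt_perturbed = ids %in% perturbed,
                      rescued = ids %in% rescued,
                      stringsAsFactors = FALSE)
  list(expr = ExpressionMatrix(counts, meta), truth = truth,
       panel = drivers, tf_universe = tf_ids)
}

# planted beta-value profiles: list of cgi-category -> function(condition)
# -> length-5 stage vector (plus scalar CC / MII levels)
.methProfiles <- function(cfg) {
  lo <- cfg$p_low; hi <- cfg$p_high
  mid <- (lo + hi) / 2 + 0.025  # two-step group passes through 0.35 at lo=0.05
  phim <- list(
    g1 = c(lo, hi, hi, hi, hi),
    g2 = c(lo, lo, hi, hi, hi),
    g3 = c(lo, lo, lo, lo, hi),
    g4 = c(lo, lo, mid, hi + 0.05, hi + 0.05),
    g5 = c(lo, lo, lo, hi, hi))
  list(lo = lo, hi = hi, phim = phim)
}

#' Simulate an RRBS methylome of a TSC derivation time course
#'
#' Plants background CGIs at a low beta-value, five PHIM groups that jump
#' to a high level at assigned stages (shared by NF/NT/SNT), donor-inherited
#' aberrations (high in the cumulus-cell CC profile, low in MII, persisting
#' through NT derivation), de novo aberrations (high only in NT/SNT
#' derivation), FGF4-stage aberrations (high only at TSC_P1/TSC_Pn in NT
#' and SNT), and SNT rescue of a configured fraction of the NT-aberrant
#' islands. Per CpG and sample column, coverage is 1 + Poisson and the
#' methylated count binomial; a dropout probability leaves CpGs undetected.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{calls} (a \linkS4class{MethylationCallSet} whose
#'   columns are replicate-level samples, including CC and MII), \code{cgis}
#'   (named GRanges) and \code{truth} (data.frame: cgi, category,
#'   phim_group, origin, rescued).
#' @export
simulateMethylome <- function(config) {
  stopifnot(inherits(config, "tscdyn_config"))
  .withSeed(config$seed + 1L, .simulateMethylomeImpl(config))
}

.simulateMethylomeImpl <- function(cfg) {
  stages <- stageLevels()
  pf <- .methProfiles(cfg)
  n <- cfg$n_cgis
  cgi_ids <- sprintf("CGI_%04d", seq_len(n))

  k <- round(c(cfg$phim_fractions, cfg$donor_ahm, cfg$denovo_ahm,
               cfg$fgf4_ahm) * n)
  if (sum(k) > n) stop("planted CGI counts exceed n_cgis")
  category <- rep(c(paste0("phim_g", 1:5), "donor_ahm", "denovo_ahm",
                    "fgf4_ahm", "background"), c(k, n - sum(k)))
  aberr <- which(category %in% c("donor_ahm", "denovo_ahm"))
  n_resc <- round(cfg$rescue_fraction * length(aberr))
  rescued_idx <- sort(sample(aberr, n_resc))
  rescued <- logical(n); rescued[rescued_idx] <- TRUE

  # CGI layout: 600 bp islands every 10 kb on one synthetic chromosome
  width <- 600L
  starts0 <- 10000L * seq_len(n)               # 0-based starts
  n_cpg <- sample(seq(cfg$cpgs_per_cgi[1L], cfg$cpgs_per_cgi[2L]),
                  n, replace = TRUE)
  cpg_pos <- unlist(lapply(seq_len(n), function(i)
    starts0[i] + sort(sample.int(width, n_cpg[i])) - 1L))
  cpg_cgi <- rep(seq_len(n), n_cpg)
  cgis <- GRanges("chr1", IRanges(starts0 + 1L, starts0 + width))
  names(cgis) <- cgi_ids

  # per-CGI beta value for (condition, stage)
  pMat <- function(cond) {
    p <- matrix(pf$lo, n, 5L, dimnames = list(cgi_ids, stages))
    for (g in 1:5) {
      sel <- category == paste0("phim_g", g)
      if (any(sel))
        p[sel, ] <- matrix(pf$phim[[g]], sum(sel), 5L, byrow = TRUE)
    }
    if (cond %in% c("NT", "SNT")) {
      high <- category %in% c("donor_ahm", "denovo_ahm")
      if (cond == "SNT") high <- high & !rescued
      p[high, ] <- pf$hi
      p[category == "fgf4_ahm", c("TSC_P1", "TSC_Pn")] <- pf$hi
    }
    p
  }
  pCC <- ifelse(category == "donor_ahm", pf$hi, pf$lo)
  pMII <- rep(pf$lo, n)

  meta <- rbind(
    expand.grid(replicate = seq_len(cfg$meth_replicates), stage = stages,
                condition = c("NF", "NT", "SNT"), stringsAsFactors = FALSE),
    expand.grid(replicate = seq_len(cfg$meth_replicates), stage = "none",
                condition = c("CC", "MII"), stringsAsFactors = FALSE))
  meta <- meta[, c("condition", "stage", "replicate")]
  meta$sample_id <- sprintf("%s_%s_r%d", meta$condition,
                            ifelse(meta$stage == "none", "x", meta$stage),
                            meta$replicate)
  meta$sample_id <- sub("_x_", "_", meta$sample_id)

  ncpg_all <- length(cpg_pos)
  meth <- total <- matrix(NA_integer_, ncpg_all, nrow(meta))
  pcond <- list(NF = pMat("NF"), NT = pMat("NT"), SNT = pMat("SNT"))
  for (j in seq_len(nrow(meta))) {
    p_cgi <- switch(meta$condition[j],
                    CC = pCC, MII = pMII,
                    pcond[[meta$condition[j]]][, meta$stage[j]])
    p <- p_cgi[cpg_cgi]
    tot <- 1L + stats::rpois(ncpg_all, cfg$coverage_mean - 1)
    det <- stats::runif(ncpg_all) >= cfg$dropout
    m <- stats::rbinom(ncpg_all, tot, p)
    total[det, j] <- tot[det]
    meth[det, j] <- m[det]
  }
  colnames(meth) <- colnames(total) <- meta$sample_id

  phim_group <- rep(NA_integer_, n)
  isph <- grepl("^phim_g", category)
  phim_group[isph] <- as.integer(sub("phim_g", "", category[isph]))
  truth <- data.frame(
    cgi = cgi_ids, category = category, phim_group = phim_group,
    origin = ifelse(category == "donor_ahm", "donor",
                    ifelse(category %in% c("denovo_ahm", "fgf4_ahm"),
                           "de_novo", NA_character_)),
    rescued = rescued, stringsAsFactors = FALSE)
  calls <- MethylationCallSet(rep("chr1", ncpg_all), cpg_pos, meth, total, meta)
  list(calls = calls, cgis = cgis, truth = truth)
}

#' Write a complete simulated dataset to a directory
#'
#' Emits counts TSV, per-sample CpG reports, CGI BED, a TSS table placing
#' each of the first genes inside successive CGIs, the TF list, truth
#' tables, and the resolved configuration as YAML.
#'
#' @param config a \code{\link{simConfig}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- simulateExpression(config)
  me <- simulateMethylome(config)
  writeCounts(ex$expr, file.path(dir, "counts.tsv"))
  .writeTsv(sampleMeta(ex$expr), file.path(dir, "samples_rna.tsv"))
  .writeTsv(sampleMeta(me$calls), file.path(dir, "samples_rrbs.tsv"))
  writeBed(me$cgis, file.path(dir, "cgis.bed"))
  for (s in colnames(me$calls))
    writeCpgReport(me$calls, file.path(dir, paste0("cpg_", s, ".tsv")), s)
  # TSS table: gene i sits inside CGI i where possible, downstream otherwise
  ids <- rownames(ex$expr)
  ncgi <- length(me$cgis)
  tss <- data.frame(gene_id = ids, chrom = "chr1",
                    tss = ifelse(seq_along(ids) <= ncgi,
                                 start(me$cgis)[pmin(seq_along(ids), ncgi)] + 249L,
                                 10000L * seq_along(ids) + 5000L),
                    strand = "+")
  .writeTsv(tss, file.path(dir, "tss.tsv"))
  writeLines(ex$tf_universe, file.path(dir, "tf_list.txt"))
  .writeTsv(ex$truth, file.path(dir, "truth_genes.tsv"))
  .writeTsv(me$truth, file.path(dir, "truth_cgis.tsv"))
  writeLines(yaml::as.yaml(unclass(config)), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname simConfig
#' @param path YAML file of config fields (missing fields take defaults).
#' @export
readSimConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simConfig, vals[intersect(names(vals), names(formals(simConfig)))])
}
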