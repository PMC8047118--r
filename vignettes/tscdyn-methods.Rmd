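---
title: "Methods: transcriptome and methylome dynamics of TSC derivation"
author: "tscdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome and methylome dynamics of TSC derivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tscdyn)
```

# The analysis problem

Trophoblast stem cells (TSCs) are derived from blastocysts through a fixed
five-stage course — TE3.5, TE4.5, outgrowth, TSC_P1, TSC_Pn — and the
derivation can start from naturally fertilized embryos (NF), cloned embryos
(NT, somatic cell nuclear transfer) or cloned embryos treated with the HDAC
inhibitor Scriptaid (SNT). Two molecular readouts are compared across
conditions and stages: bulk RNA-seq counts and RRBS per-CpG bisulfite
methylation calls. `tscdyn` provides the statistical machinery for that
comparison; this vignette records the models, the parameter choices, and the
places where the design was genuinely open.

# Expression model and dynamic-gene selection

Counts are normalized as `log2(RPM + 1)` with RPM = count / library size ×
10^6 (library size = column sum; no gene-length term, so within-gene
cross-sample comparisons are the intended use). A gene is "expressed" when
its normalized value exceeds 1 in at least one sample, strictly — a gene at
exactly 1 everywhere is dropped.

PCA is run on the expressed-gene matrix with samples as observations,
centered per gene and unscaled. Centering is the minimal standard choice;
scaling would up-weight low-variance genes and was deliberately not applied.
Two determinism conventions are imposed: each component's loading vector is
flipped so its largest-magnitude entry is positive, and the top-fraction
selection (default 5% per component, union over PC1 and PC2, ties at the
cutoff all included) is computed from sorted absolute loadings rather than
quantile interpolation, so the selected set is identical across platforms.
Whether the selection should use PC1 only or PC1+PC2 is configurable
(`components=`); the union of the two displayed components is the default
because the course's dominant monotone axis and its transient axis both
carry stage information.

Selected genes are clustered on z-scored stage means (replicates collapsed
to means per condition) with Ward linkage on Euclidean distance, cut at
k = 6. Each cluster is labelled from the successive stage-mean differences
of its centroid: `Pro` when no difference falls below −eps and at least one
exceeds eps, `Down` for the mirror, else `Transient`. The strictness
threshold eps defaults to 0.1 normalized units — small enough that a real
plateau does not block a Pro label, large enough that replicate noise does
not create one; it is a parameter, not biology.

Differential expression applies fixed thresholds (adjusted p < 0.01 and
|log2 fold change| > 2 by default) to a pluggable per-gene statistic. The
built-in statistic is a Welch two-sample t-test on the log2(RPM+1)
replicate values with Benjamini–Hochberg adjustment, and the fold change is
the difference of group means of normalized expression. This is a simple,
transparent test chosen because model-based count fitting is outside this
package's scope; an externally computed table (`stats=`) can be substituted
without changing the threshold semantics, and the tests exercise both
routes.

# Panel pseudotime

For a panel of n transcription-factor genes, the pseudotime of a replicate
is the linear projection `T = sum_i Exp_i * lambda_i`, where `Exp_i` is the
replicate's normalized expression of panel gene i and lambda is the PC1
loading vector of a PCA restricted to the panel genes and the NF samples.
No per-replicate fitting occurs: NT and SNT replicates are scored with the
NF-derived lambda unchanged, which is what makes cross-condition
comparisons meaningful. Because a principal-component sign is arbitrary,
lambda is flipped wholesale when T decreases with the canonical NF stage
order (Spearman < 0), so pseudotime always increases along derivation.

The resampling null draws the same number of TFs from a TF universe without
replacement, re-derives lambda on the NF samples for each random panel
(the full inference is repeated, including the sign convention), and scores
every replicate; the default is 5,000 iterations. Per replicate we keep the
mean, SD and the 5th/95th percentiles of T across iterations.

Stage-ordering is judged two ways, matching the two objects being judged:

* A **single trajectory** (the real panel) orders the course when every
  adjacent-stage gap `min(T next) − max(T current)` is positive — i.e.
  every between-stage gap exceeds the within-stage spread. When that holds,
  the Spearman correlation between T and the stage index equals its maximal
  attainable value; with r tied replicates per stage that maximum is below
  1 (0.982 for 5 stages × 3 replicates), which is how "perfect ordering" is
  asserted in the tests.
* The **null ensemble** is a distribution per replicate, not a point, so
  its per-stage intervals are the pooled 5–95% iteration ranges of the
  stage's replicates; the null "fails to order" the course when any
  adjacent intervals intersect. Summarizing the null only by its
  iteration-mean trajectory would average away exactly the panel-to-panel
  variability the resampling is meant to expose, so the interval view is
  the one the acceptance checks use.

# Methylome model

CpG calls arrive per replicate as (chrom, position, strand, methylated,
total). Opposite-strand calls of one CpG are pooled by summing counts after
shifting minus-strand positions onto the plus-strand C — CGI-level ratios,
not strand-resolved calls, are the unit of analysis, and pooling raises
coverage. A CpG absent from a sample is "not detected", which the classes
keep distinct from a detected ratio of 0.

Two retention filters precede any call:

* **CpG coverage**: a CpG is kept for a biological sample when its coverage
  is ≥ 5 in *every* replicate of that sample (the strict reading of a
  "coverage > 4 in replicates" rule); replicate counts are then pooled. An
  any-replicate mode exists (`mode = "any"`).
* **CGI detection**: an island is kept when it has ≥ 5 detected CpGs in
  *every* sample, so its ratio trajectory is comparable across stages; the
  permissive "in at least one sample" reading is again available behind the
  same flag.

CGI methylation is the unweighted mean of its detected CpG ratios — not the
pooled-count ratio, which would weight CpGs by coverage; pooled counts are
kept alongside because the Fisher exact test for differential islands does
operate on the pooled 2×2 table (the test needs counts, and pooling is the
only aggregation that preserves them). A differential call requires both a
ratio difference > 0.25 and Fisher p < 0.05; a "highly methylated" island
is strictly above ratio 0.25.

**PHIM** (progressively changing) islands have a maximal absolute
adjacent-stage difference > 0.25 within one condition's five-stage course;
an alternative global max-minus-min criterion is selectable because both
readings of "maximal difference during derivation" are defensible, and the
adjacent reading is the default since it is the one the K-means grouping is
built on. PHIM islands are grouped by K-means (k = 5) on their 4-vector of
adjacent-stage deltas, with a fixed seed and 10 restarts keeping the best
inertia, for determinism.

**AHM/ALM** (aberrantly highly/lowly methylated) islands deviate by more
than 0.25 from the matched stage of the reference condition (NF by
default); swapping test and reference provably swaps the two labels. An NT
AHM island is *corrected* when it is not AHM in SNT at the same stage; the
corrected/uncorrected split partitions the NT AHM set exactly, by
construction. Donor origin attributes a derivation aberration to the donor
genome when the island is also AHM in the cumulus-cell (CC) versus MII
oocyte comparison; the inherited fraction is reported with a hypergeometric
enrichment against the retained-CGI universe.

Promoter classes use a linear-weighted CpG density in a 300-bp window
around the TSS: a CpG at distance d contributes `1 − d/150`, the natural
reading of "linear" weighting (the center CpG counts 1, the window edge 0).
The HCP/ICP/LCP thresholds are configuration values with no built-in
defaults pretending to be biology, because the class definitions are
conventionally inherited from prior literature rather than re-derived.
CGI–gene association measures distance from the island boundary (0 for a
TSS inside), associates within 5 kb, and breaks exact-distance ties
lexicographically (logged) for reproducibility.

# Enrichment statistics

Set overlaps are tested with the upper-tail hypergeometric probability
P(X ≥ k) — every use in this pipeline asks about over-representation — and
quantified by the representation factor RF = k/(nA·nB/N). The
over-representation score combines the two as `log2(RF) × (−log10 p)`, so
enrichment scores positive; the variant with a literal `log10 p` factor
(negative for enrichment) is available (`literal = TRUE`) since both sign
conventions circulate. Paired comparisons use a two-sided paired t-test
with Holm step-down adjustment; a comparison whose paired differences are
all exactly zero is degenerate and returns p = 1 by convention, and a
constant nonzero difference returns p = 0 (perfect separation).

# The synthetic-data generator

The generator is first-class, tested code: it plants precisely the
structures the analysis assumes and emits truth tables, so every downstream
stage has a parameter-recovery test with no external download.

*Expression.* Counts are negative binomial (mean–dispersion
parameterization, default dispersion 0.05) around per-(gene, stage,
condition) means defined on the log2(RPM+1) scale, with an extra
multiplicative log2-normal replicate jitter of SD 0.2 normalized units.
Six trend clusters are planted: three Pro shapes (rising from TE4.5
saturating; rising from outgrowth; shallow outgrowth rise with a steep late
phase), one Down shape, and V / inverted-V transients, each spanning about
6 normalized units. The 75 driver TFs (20/40/40 across the Pro clusters)
carry the full amplitude; other planted genes follow with amplitude 0.3–0.6
of the profile, reflecting targets downstream of the drivers — this is also
what makes "drivers dominate the PC loadings" a property of the data rather
than an accident. In NT, cluster-2/3 driver means at outgrowth are
multiplied by 0.25; SNT restores a configured fraction (default 0.8) of
them. Defaults: 2,000 genes, 300 TFs, 3 replicates per stage per condition,
library size 2×10^6.

*Methylome.* Per CpG and sample column, coverage is 1 + Poisson(mean − 1)
(default mean 30) with a 5% detection dropout, and the methylated count is
binomial at the island's planted beta value: background 0.05 everywhere;
five PHIM groups jumping to 0.6 at TE4.5, outgrowth, TSC_Pn, a two-step
group, and TSC_P1 respectively; donor-inherited aberrations high in the CC
profile, low in MII, persisting through NT derivation; de novo aberrations
high only in NT/SNT; FGF4-stage aberrations high only at TSC_P1/TSC_Pn in
NT and SNT. SNT rescues a configured fraction of the NT-aberrant islands
(donor and de novo alike — the rescue acts on the aberration, not on its
origin). The de novo class exists so that donor-origin recovery has a
planted inherited fraction below 1. Defaults: 600 islands of 8–20 CpGs,
2 RRBS replicates.

*What the generator does not emulate.* Replicate noise is i.i.d. given
(stage, condition): no batch structure, no mate/litter effects. Coverage is
independent per CpG: no RRBS fragment-selection correlation along an
island. There is no read-level error, no non-CpG methylation, no allelic or
imprinting structure. Passing recovery tests therefore demonstrates that
the statistics recover the structures they target at realistic noise and
coverage — not that they are robust to batch confounding or
fragment-level artefacts in real RRBS.

# Numerical and degenerate-case choices

* PCA of an all-identical-sample matrix returns zero scores (no error).
* Welch t with zero variance in both groups returns p = 1 when means are
  equal, p = 0 otherwise.
* K-means and the resampling null take explicit seeds; the null restores
  the caller's RNG state afterwards.
* `rf = 0` yields an over-representation score of −Inf with a warning
  rather than an error, so tabulated scans do not abort.
* Fisher tests are delegated to `stats::fisher.test`; the test suite pins
  them (and `stats::phyper`) against independent enumeration oracles over
  all small instances.

# Problem sizes used by the checks

The recovery checks run at the design's own scale: 2,000 genes × 45
RNA samples, a 20-seed sweep for pseudotime with a 500-iteration null per
seed (the default for analysis remains 5,000), 400-island runs with
200 planted 0.30- versus 0.20-jumps for PHIM operating characteristics,
and a 2,000-island run with 500 donor-inherited plus 333 de novo
aberrations (inherited fraction 0.6) at rescue fraction 0.8 for the
rescue and origin accounting. The rescued-gene intersection is computed on
a 5-replicate run (the upper bound of the design's replicate range) at
adjusted p < 0.05 and |lfc| > 1: a two-sample t-test at three replicates
has essentially no power at an FDR of 0.01, and the planted 4-fold
down-shift has an asymptotic log2 fold change of exactly 2, so the
canonical (0.01, 2) cutoffs would measure the thresholds, not the
recovery.

# Known limitations

* The built-in DEG statistic is not a count-model test; for real data with
  strong mean–variance structure an external table from a dedicated tool
  should be supplied.
* Pseudotime is a linear projection; it assumes the panel's expression
  changes monotonically along the course and will fold back a trajectory
  whose drivers are non-monotone.
* CGI ratios from few detected CpGs are noisy; the strict retention
  default trades coverage of the CGI universe for cross-stage
  comparability.
* The CC-vs-MII donor comparison treats the oocyte profile as the clean
  reference; sperm contribution is ignored on the grounds that CGIs are
  essentially unmethylated in sperm.
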