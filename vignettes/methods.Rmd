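---
title: "Genome architecture of sex-biased expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome architecture of sex-biased expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexbiasarch)
```

# Scope

`sexbiasarch` analyses how sex-biased gene expression is organized along a
genome: which genes are male- or female-biased in each of several tissues
(here, three pairs of legs in a sexually dimorphic insect), whether those
genes pile up on the X chromosome, in multi-megabase genomic regions, or in
runs of adjacent genes, and whether sex-biased genes evolve faster at the
sequence level.  Every analysis is driven either by user-supplied tables
(annotation, counts, coverage, dN/dS) or by the package's own synthetic
generator, which plants known effects so each detector can be tested
against ground truth.

# The synthetic study design

The generator emulates a two-line, two-sex, three-leg RNA-seq design with
three replicates per cell: 36 libraries in all.  The genome is 13 large
scaffolds (12 autosomes and one X), 5 Mb each by default, with genes placed
at exponential inter-start gaps of mean 20 kb (minimum 1 kb), so a 2 Mb
window holds roughly 100 genes with realistic Poisson-like variation in
the per-window count — variation a fixed grid would hide from the window
scanner.

Counts are negative binomial.  Per-gene baseline means are log-normal with
meanlog 3 and sdlog 1.8 (on the count scale): this puts a realistic
minority of genes under the 2-FPKM expression filter rather than making
every annotated gene "expressed".  Dispersion is 0.05, a conventional bulk
RNA-seq value; the source data give no dispersion estimate to fit, so these
defaults are conventional, not fitted.  Library-size factors are log-normal
with sd 0.2, large enough that unnormalized analyses would visibly fail —
normalization has to matter in the tests.

Planted effects, all recorded in a `truth_set`:

* **Sex bias.** Per leg, a configured fraction of genes is male- or
  female-biased (defaults 2/2/6 % male and 4/4/10 % female for legs
  1/2/3, mirroring a third-leg-exaggerated phenotype); a male-biased gene
  has its expected count multiplied by `2^effect_log2fc` (default 4x) in
  male samples of that leg.
* **Leg and line effects.** 5 % of genes are up in leg 3 of both sexes;
  10 % carry a line effect, which the within-class PCA and the pooled-line
  DE design have to absorb.
* **Regions and clusters.** Explicit multi-megabase spans (with a chosen
  number of member genes) and runs of 2–4 consecutive genes can be forced
  to one direction, the targets of the two architecture detectors.
* **The X.** The X scaffold gets half male genomic coverage; expression is
  simulated fully dosage-compensated (equal expected expression in both
  sexes), making the dosage test a calibrated null unless an explicit male
  down-shift is configured.  A feminization factor re-weights where
  female-biased genes land (X versus autosomes) without changing their
  per-leg totals.

One master seed is split deterministically per generator, so each stage is
independently reproducible; per-leg planted label counts equal
`round(fraction * n_genes)` exactly (region and cluster planting then
override their member genes, adding to those totals).

What the generator does **not** emulate: isoforms and transcript-level
quantification, GC or length biases, correlated gene-gene expression,
outlier samples, or a fragmented assembly.  Passing tests therefore show
the detectors behave correctly under the design's statistical assumptions,
not that any particular real dataset satisfies those assumptions.

# Bias calling

Counts are converted to FPKM and TPM using annotated gene spans as
effective lengths.  A gene is expressed in a leg unless its FPKM is below
2 in more than half of that leg's 12 samples, or its mean FPKM is below 2
in both sexes ("below" is strict, so a gene at exactly 2 FPKM stays).

The differential stage is deliberately pluggable.  The shipped stand-in
normalizes by median-of-ratios size factors, sets
`log2FC = log2((mean_A + 0.5)/(mean_B + 0.5))` on normalized group means,
takes p-values from a two-sided rank-sum test and adjusts them by
Benjamini–Hochberg within the contrast.  Sex contrasts pool the two lines
(the combined design both lines share), with line recorded as a blocking
label; a per-line mode exists for overlap checks.  Any external
differential table with `gene_id`, `baseMean`, `log2FC`, `padj` can be
substituted — all downstream analyses consume only those columns.

A gene is called **male-biased** when `log2FC > log2(1.5)` and
`padj < 0.05`, **female-biased** symmetrically; fold change is interpreted
on the linear scale, i.e. |log2FC| > log2(1.5) ≈ 0.585.  For the window
scan, log2FC is then *reassigned*: unexpressed genes get 0 with p = 1,
unbiased genes get 0, biased genes keep their estimate.  This reassignment
is what lets a window mean measure only the contribution of called
sex-biased genes.

Reported percentages are rounded half away from zero to two decimals, the
rounding that reproduces published summary tables digit for digit
(`summarize_bias` on counts 161/8950, 166/8706, 524/8710 male-biased gives
1.80, 1.91, 6.02 %).

# Chromosome-level analyses

**X identification.** Males are hemizygous, so among the 13 largest
scaffolds the X is the unique one whose male genomic depth is about half
the median of the others.  "About half" is a ratio band of [0.35, 0.65];
the source rule gives no tolerance, and this band absorbs Poisson depth
noise down to ~30x while never admitting a full-coverage scaffold.  No or
multiple candidates leave the X unassigned with per-scaffold diagnostics.

**Y scan.** Among the 50 largest scaffolds, an X-like coverage ratio plus
*exclusively* male-biased expressed genes flags a Y candidate; a true X is
excluded by its mixed male/female-biased gene content.

**Dosage compensation.** Per leg, X genes with FPKM > 2 in at least half
the samples are kept; expression is averaged over replicates and lines
within each sex, and male versus female per-gene log2 mean FPKM are
compared by a two-sided rank-sum test, the gene being the unit of
observation.

**Enrichment.** X-versus-autosome over- or under-representation of biased
genes uses a 2x2 Fisher exact test over the leg's expressed genes on the X
plus the 12 largest autosomes (two-sided by the point-probability method;
the reported odds ratio is the conditional MLE).  Whether the universe
should be expressed or all annotated genes is not fully determined by the
source description; expressed-per-leg is the default, with
`universe = "annotated"` exposed.  The same machinery tests the
sex-by-leg regulatory crosstalk (are leg-3 male-biased genes also
up in leg 3?), reporting the overlap count and its percentage.

# The sliding-window region scan

Each scaffold is split into 100-kb bins; a gene belongs to the bin holding
its midpoint (half-open bins, so each gene counts exactly once per
window).  A 2-Mb window (20 bins) slides in 1-bin steps; truncated windows
at scaffold ends are dropped; windows with fewer than 5 member genes are
never called.  The statistic per window is the mean reassigned log2FC of
its member genes.

The null must respect the mean–variance structure of log2FC: lowly
expressed genes have noisier fold changes and are likelier to be called at
a large |log2FC|.  Genes are therefore stratified into 5 baseMean quantile
categories (boundary ties to the lower stratum; unexpressed genes in
stratum 1) and each permutation shuffles the reassigned values across gene
positions *within* each stratum, then recomputes all window means.  The
implementation materializes a sparse window-by-gene incidence matrix once
and evaluates each block of permutations as one sparse-dense product;
per-window exceedance counts and the top/bottom 0.5 % order statistics are
accumulated streaming, so memory stays bounded at the production setting
of 100,000 permutations (quantile queries beyond 99.5 % are exact).

Calling uses the add-one empirical p-value,
`p_upper = (1 + #{perm >= obs})/(n_perm + 1)`, against a per-window alpha
of `1 - quantile_cutoff` (1e-4 at the default 99.99 % cutoff).  Two
numerical choices deserve a note:

* The source procedure mentions both a correction over the ~300
  independent windows and the 99.99 % cutoff, without fixing their
  composition.  The default here treats the 99.99 % quantile as the
  already-corrected per-window threshold; `bonferroni = TRUE` additionally
  divides alpha by `n_independent` (auto-computed as total length /
  window span, and always reported).
* At reduced permutation counts the configured alpha can drop below the
  resolution `1/(n_perm + 1)` of the permutation sample — at 2,000
  permutations the smallest achievable p is ~5e-4 > 1e-4.  The effective
  alpha is therefore floored at `1/(n_perm + 1)`: below the floor the rule
  is "observed mean more extreme than every permutation", the natural
  finite-sample estimate of the quantile rule.  At the production
  100,000 permutations the floor is inactive.

Adjacent or overlapping same-direction significant windows are merged into
maximal regions and their member biased genes listed.

# Consecutive-gene clusters

Genes are ordered along each scaffold and maximal runs of >= 2 adjacent
same-direction biased genes are recorded; any unbiased gene, an
opposite-direction gene, or a scaffold boundary breaks a run.  The summary
statistic is the clustered proportion: biased genes inside runs over all
biased genes of that direction, plus a cluster-size histogram.

The null shuffles the observed label multiset across all gene positions
(genome-wide over the concatenated scaffolds by default, preserving each
scaffold's gene count; per-scaffold shuffling is available) 1,000 times
and reports means and central 95 % fluctuation intervals.  An observed
statistic outside the interval is flagged, with the side giving the
direction.  For interior genes at label density p the null clustered
proportion is approximately `1 - (1 - p)^2`, a closed form the tests use
as an independent check of the machinery.  The label universe (all
annotated genes versus expressed genes) materially changes the null
density; all-annotated is the default and the alternative is a parameter.

# dN/dS comparisons and the label bootstrap

Per-gene dN/dS ratios (genes with dS = 0 are excluded, with the count
reported) are compared between bias categories by two-sided rank-sum
tests.  Because the male-biased category is small and dN/dS distributions
are heavy-tailed, a significant rank-sum p alone is weak evidence; the
label-permutation bootstrap guards it.  Each of 1,000 iterations sets all
genes unbiased, draws 253 "male" and 463 "female" labels without
replacement, and recomputes both comparisons.  The cutoff is the empirical
p-value that 99.95 % of bootstrap p-values exceed (the lower 0.05 % order
statistic, quantile type 1); an observed p below the cutoff cannot easily
be produced by random labelling.  The cutoff is data-dependent by
construction and is reported, never hard-coded.

A sex-by-leg cross-classification (`stratify_by_leg_bias`) lets the same
comparison isolate which combination — e.g. genes both male- and
leg-biased — carries a sequence-evolution signal.

# Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive internally (the R/Bioconductor and
  GFF3 convention); BED input/output is converted at the boundary, and
  window/region coordinates in outputs are 0-based half-open bp.
* Rank-sum tests use the exact null when sample sizes are small and ties
  absent, otherwise the normal approximation without continuity
  correction, so identical multisets give p = 1 exactly; fully tied
  samples (zero variance) also give p = 1.
* Fisher tables with an empty margin return p = 1 with the odds ratio
  flagged undefined; an infinite conditional-MLE odds ratio is flagged
  rather than silently truncated.
* All-zero count columns produce zero FPKM/TPM with a warning; constant
  expression matrices give zero variance fractions in the PCA.
* Every stochastic routine takes a seed; the pipeline derives per-stage
  seeds from one master seed, and stage outputs carry the seed plus a
  config hash (the output directory is excluded from the hash).

# Problem sizes used by the test-suite

The shipped tests exercise the production code paths at reduced
Monte-Carlo sizes, chosen so the full suite runs on a laptop-class single
core: 2,000 permutations for the window scan (the production default is
100,000), 1,000 iterations for cluster and bootstrap nulls, 13 x 5 Mb
genomes with ~3,400 genes, and 20–200 seeded replicates per calibration
experiment.  The same statistics at production sizes only narrow the
Monte-Carlo intervals; they do not change any decision rule.

# Known limitations

* The DE stand-in is a rank-sum screen, not a negative-binomial model; at
  n = 6 vs 6 its discrete p-values limit sensitivity near the threshold.
  It exists so the architecture analyses can be exercised end-to-end, and
  real differential tables are first-class inputs.
* Effective gene length equals the annotated span; transcript-level
  quantification summed to genes is out of scope.
* The region scan's independence count treats windows as tiling blocks;
  overlapping windows are positively correlated, which is why calls are
  merged before interpretation.
* No FDR alternative to the quantile/Bonferroni rule, no smoothing
  variant, and no cross-species region comparison are provided.
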