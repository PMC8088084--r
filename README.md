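# sexbiasarch

Genome architecture of sex-biased gene expression: simulation and analysis
of where male- and female-biased genes sit in a genome, for a two-line x
two-sex x three-tissue RNA-seq design (the kind used to study exaggerated,
sexually dimorphic traits such as male rear legs in water striders).

Given a gene annotation, per-sample counts (plus a sample sheet), male
genomic coverage per scaffold and an optional per-gene dN/dS table — or a
fully synthetic study generated with planted ground truth — the package:

* calls per-leg **sex-biased genes**: a gene is male-biased when its fold
  change exceeds 1.5 (|log2FC| > log2 1.5) at adjusted p < 0.05, after an
  expression filter (FPKM >= 2 in at least half the leg's samples, or mean
  FPKM >= 2 in one sex);
* identifies the **X chromosome** as the unique large scaffold with ~half
  male genomic coverage, scans for Y candidates, tests **dosage
  compensation** (male vs female per-gene log2 FPKM on the X, rank-sum) and
  X-vs-autosome enrichment of biased genes (Fisher exact);
* scans for **large enriched regions** with 2-Mb sliding windows (100-kb
  step): per-window mean *reassigned* log2FC (unbiased/unexpressed genes
  set to 0) is compared against an expression-stratified permutation null
  — log2FC values shuffled within 5 baseMean quantile strata, 100,000
  permutations at production scale — and windows beyond the 99.99% null
  quantile are merged into regions;
* detects **runs of consecutive same-direction biased genes** along gene
  order and tests the clustered proportion against 95% fluctuation
  intervals from 1,000 label permutations;
* compares **dN/dS** between bias categories (rank-sum) and guards the
  result with a label-permutation bootstrap: 253 "male" and 463 "female"
  labels redrawn at random 1,000 times, observed p declared non-random
  only when below the cutoff that 99.95% of bootstrap p-values exceed.

A negative-binomial simulator (13 scaffolds, ~1 gene / 20 kb, 36 samples,
planted sex/leg/line effects, a feminizable half-coverage X, plantable
regions and clusters, gamma dN/dS categories) provides the ground truth
that the test-suite uses to verify recovery and calibration of every
detector.

## Worked example

```r
library(sexbiasarch)

cfg <- pipeline_config(
  synthetic  = simulation_config(seed = 3),
  region_cfg = region_scan_config(n_perm = 2000),
  outdir     = "run1", seed = 3)
res <- run_pipeline(cfg)
res$summary$table
#>   leg n_expressed n_male pct_male n_female pct_female
#> 1   1        3097     55     1.78      114       3.68
#> 2   2        3103     56     1.80      104       3.35
#> 3   3        3076    182     5.92      303       9.85
res$chrom$x$x_scaffold_id
#> [1] "scaffold_13"
round(res$chrom$x$ratio, 3)
#> [1] 0.502
```

The summary table is the per-leg census: of the ~3,100 expressed genes per
leg, ~2% are male-biased in legs 1–2 versus ~6% in the exaggerated third
leg (the planted gradient), with female-biased genes roughly twice as
common — the asymmetry the architecture analyses then localize.  The X is
recovered from its 0.50 male coverage ratio.  `run1/` holds every stage
output (bias calls, window statistics, enriched-region BED, cluster
summaries, dN/dS JSON) plus a manifest with seed and config hash;
rerunning with the same seed reproduces every file byte for byte.

On real data, replace `synthetic` with file paths
(`annotation_path`, `counts_path`, `samples_path`, `coverage_path`,
`dnds_path`); externally computed differential tables can be used in place
of the built-in rank-sum stand-in, which exists only so the pipeline runs
end-to-end without a DE package.

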