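Package: sexbiasarch
Title: Genome Architecture of Sex-Biased Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of the genomic architecture of
    sex-biased gene expression in a two-line, two-sex, three-leg RNA-seq
    design. Provides a negative-binomial count simulator with planted
    sex-, leg- and line effects on a multi-scaffold genome with a
    half-coverage X chromosome; FPKM/TPM abundance and expression
    filtering; a rank-sum differential-expression stand-in and sex-bias
    calling at fold-change and adjusted-p thresholds; X-chromosome
    identification from male genomic coverage, Y-candidate scanning,
    dosage-compensation tests and X-versus-autosome Fisher enrichment;
    an expression-stratified sliding-window permutation scan for large
    genomic regions enriched in sex-biased genes; detection of runs of
    consecutive same-direction sex-biased genes with permutation
    fluctuation intervals; and Wilcoxon dN/dS category comparisons
    guarded by a label-permutation bootstrap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
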