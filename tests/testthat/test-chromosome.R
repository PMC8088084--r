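cov_table <- function(depths, lengths = NULL) {
  n <- length(depths)
  data.frame(scaffold_id = sprintf("s%02d", seq_len(n)),
             length = lengths %||% seq(5e6, by = -1e4, length.out = n),
             mean_depth = depths)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("X identification applies the half-coverage band rule", {
  xa <- identify_x(cov_table(c(rep(100, 12), 50)))
  expect_equal(xa$x_scaffold_id, "s13")
  expect_equal(xa$ratio, 0.5)

  expect_true(is.na(identify_x(cov_table(rep(100, 13)))$x_scaffold_id))
  # ratio 0.7 lies outside [0.35, 0.65]
  expect_true(is.na(identify_x(cov_table(c(rep(100, 12),
                                           70)))$x_scaffold_id))
  # two half-coverage scaffolds -> ambiguous, unassigned
  expect_true(is.na(identify_x(cov_table(c(rep(100, 11), 50,
                                           50)))$x_scaffold_id))
  expect_error(identify_x(cov_table(numeric())), "empty")
})

test_that("X assignment is invariant to scaffold ordering", {
  tab <- cov_table(c(rep(100, 12), 50))
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(identify_x(perm)$x_scaffold_id, identify_x(tab)$x_scaffold_id)
})

test_that("Y scan flags only half-coverage scaffolds with male-only expression", {
  cov <- cov_table(c(rep(100, 11), 52, 50))
  ann <- data.frame(gene_id = paste0("g", 1:6),
                    scaffold = c("s12", "s12", "s13", "s13", "s01", "s01"),
                    start = c(1, 100, 1, 100, 1, 100) * 1000,
                    end = c(50, 150, 50, 150, 50, 150) * 1000 + 500)
  calls <- data.frame(gene_id = paste0("g", 1:6),
                      label = c("male", "male",        # s12: male-only
                                "male", "female",      # s13: mixed (the X)
                                "male", "unbiased"))   # s01: full coverage
  got <- scan_y_candidates(cov, calls, ann, x_id = "s13")
  expect_equal(got, "s12")
  # mixed-bias half-coverage scaffold is not flagged
  expect_false("s13" %in% got)
  # no candidates on a clean genome
  cfg <- small_sim_config()
  annS <- generate_annotation(cfg)
  sim <- generate_counts(annS, cfg)
  covS <- generate_coverage(annS, cfg)
  callsS <- data.frame(gene_id = annS$gene_id,
                       label = sim$truth$bias$leg1)
  expect_length(scan_y_candidates(covS, callsS, annS, "scaffold_04"), 0)
})

test_that("planted Y-like scaffold is recovered end to end", {
  cfg <- simulation_config(seed = 17, y_like = TRUE)
  ann <- generate_annotation(cfg)
  sim <- generate_counts(ann, cfg)
  cov <- generate_coverage(ann, cfg)
  xa <- identify_x(cov)
  expect_equal(xa$x_scaffold_id, "scaffold_13")
  calls <- data.frame(gene_id = ann$gene_id, label = sim$truth$bias$leg1)
  expect_true("scaffold_14" %in%
                scan_y_candidates(cov, calls, ann, xa$x_scaffold_id))
})

test_that("dosage test is null for equal means, rejects a male downshift", {
  ann <- data.frame(gene_id = paste0("x", 1:120), scaffold = "sX",
                    start = (1:120) * 1e4, end = (1:120) * 1e4 + 2000)
  samples <- data.frame(sample_id = paste0("s", 1:12),
                        sex = rep(c("M", "F"), each = 6), leg = 1)
  base <- matrix(rep(2^seq(2, 8, length.out = 120), 12), 120, 12,
                 dimnames = list(ann$gene_id, samples$sample_id))
  res <- test_dosage_compensation(base, ann, "sX", samples, legs = 1)
  expect_equal(res$p.value, 1)

  shifted <- base
  shifted[, samples$sex == "M"] <- shifted[, samples$sex == "M"] / 4
  res2 <- test_dosage_compensation(shifted, ann, "sX", samples, legs = 1)
  expect_lt(res2$p.value, 0.05)
  expect_lt(res2$median_log2_male, res2$median_log2_female)

  few <- ann[1:3, ]
  expect_warning(
    test_dosage_compensation(base[1:3, ], few, "sX", samples, legs = 1),
    "fewer than 5")
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  tab <- matrix(c(5, 5, 10, 80), 2, byrow = TRUE)
  expect_equal(sexbiasarch:::fisher_2x2(tab)$p.value, fisher_p_oracle(tab))
  set.seed(12)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 8), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    expect_equal(sexbiasarch:::fisher_2x2(t2)$p.value, fisher_p_oracle(t2),
                 tolerance = 1e-10)
    # invariance under transposition
    expect_equal(sexbiasarch:::fisher_2x2(t(t2))$p.value,
                 sexbiasarch:::fisher_2x2(t2)$p.value)
  }
})

test_that("X enrichment finds planted feminization and is null otherwise", {
  mk_calls <- function(ann, labels) {
    data.frame(gene_id = ann$gene_id, label = labels)
  }
  cfg <- simulation_config(seed = 23, x_feminization_factor = c(1, 1, 4))
  ann <- generate_annotation(cfg)
  sim <- generate_counts(ann, cfg)
  for (lg in c(1, 3)) {
    fr <- fisher_x_enrichment(mk_calls(ann, sim$truth$bias[[paste0("leg",
                                                                   lg)]]),
                              ann, "scaffold_13", "female")
    if (lg == 3) expect_lt(fr$p.value, 0.05) else expect_gt(fr$p.value, 0.05)
  }
  # no biased genes at all -> degenerate margin, p = 1
  fr0 <- fisher_x_enrichment(mk_calls(ann, rep("unbiased", nrow(ann))),
                             ann, "scaffold_13", "female",
                             universe = "annotated")
  expect_equal(fr0$p.value, 1)
})

test_that("direction labels agree with the odds ratio", {
  up <- sexbiasarch:::fisher_2x2(matrix(c(20, 5, 10, 40), 2))
  down <- sexbiasarch:::fisher_2x2(matrix(c(2, 30, 30, 20), 2))
  expect_equal(up$direction_label, "enriched")
  expect_gt(up$odds_ratio, 1)
  expect_equal(down$direction_label, "depleted")
  expect_lt(down$odds_ratio, 1)
})

test_that("crosstalk reports the printed-style overlap fraction", {
  # the arithmetic the crosstalk fraction reports: 84 of 524 -> 16.03%
  expect_equal(percentage(84, 524), 16.03)

  set.seed(5)
  n <- 400
  ids <- paste0("g", 1:n)
  sex_lab <- rep("unbiased", n); sex_lab[sample(n, 60)] <- "male"
  leg_lab <- rep("unbiased", n); leg_lab[sample(n, 80)] <- "male"
  sc <- data.frame(gene_id = ids, label = sex_lab)
  lc <- data.frame(gene_id = ids, label = leg_lab)
  ct <- crosstalk_enrichment(sc, lc)
  expect_equal(ct$overlap, sum(sex_lab == "male" & leg_lab == "male"))
  expect_equal(ct$fraction_pct, percentage(ct$overlap, ct$n_sex_biased))

  # all sex-biased genes also leg-biased -> infinite sample OR flagged
  sc2 <- data.frame(gene_id = ids[1:20],
                    label = rep(c("male", "unbiased"), each = 10))
  lc2 <- data.frame(gene_id = ids[1:20],
                    label = c(rep("male", 10), rep("unbiased", 10)))
  ct2 <- crosstalk_enrichment(sc2, lc2)
  expect_true(ct2$fisher$or_infinite)
  # universe mismatch is an error
  expect_error(crosstalk_enrichment(sc, lc[1:100, ]), "universe")
})

test_that("crosstalk p-values are near-uniform under label independence", {
  set.seed(99)
  n <- 2000
  ids <- paste0("g", 1:n)
  ps <- replicate(300, {
    s <- rep("unbiased", n); s[sample(n, 200)] <- "male"
    l <- rep("unbiased", n); l[sample(n, 300)] <- "male"
    crosstalk_enrichment(data.frame(gene_id = ids, label = s),
                         data.frame(gene_id = ids, label = l))$fisher$p.value
  })
  expect_lt(mean(ps < 0.05), 0.09)
  # exact-test p-values are discrete and conservative: check validity
  # (empirical CDF never exceeds the uniform beyond sampling noise)
  ks <- suppressWarnings(ks.test(ps, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})
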