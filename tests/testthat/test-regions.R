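toy_annotation <- function(starts, ends, scaffold = "s1", len = NULL) {
  ann <- data.frame(gene_id = sprintf("g%02d", seq_along(starts)),
                    scaffold = scaffold, start = starts, end = ends)
  attr(ann, "scaffold_lengths") <-
    setNames(rep(len %||% max(ends), length(unique(scaffold))),
             unique(scaffold))
  ann
}

test_that("bin assignment follows the midpoint half-open convention", {
  cfg <- region_scan_config(n_perm = 100)
  ann <- toy_annotation(c(149000, 99000, 1), c(151000, 101000, 100),
                        len = 1e6)
  bm <- assign_bins(ann, cfg)
  expect_equal(bm$bin, c(1, 1, 0))  # midpoints 150000, 100000, 50

  # hand-enumerated toy of 7 genes
  starts <- c(1, 5e4, 1.2e5, 2.5e5, 2.99e5, 3.01e5, 9e5)
  ann7 <- toy_annotation(starts, starts + 1999, len = 1e6)
  expect_equal(assign_bins(ann7, cfg)$bin,
               ((starts + starts + 1999) %/% 2) %/% 1e5)

  bad <- toy_annotation(5e5, 6e5, len = 4e5)
  expect_error(assign_bins(bad, cfg), "beyond scaffold")
})

test_that("window means equal a naive rescan and basic arithmetic", {
  cfg <- region_scan_config(window_bins = 5, n_perm = 100,
                            min_genes_per_window = 1)
  set.seed(8)
  starts <- sort(sample(1:(2e6 - 3000), 90))
  ann <- toy_annotation(starts, starts + 2000, len = 2e6)
  vals <- setNames(sample(c(0, 0, 0, 1.5, -2), 90, TRUE), ann$gene_id)
  lens <- attr(ann, "scaffold_lengths")
  ws <- compute_window_means(vals, assign_bins(ann, cfg), cfg, lens)
  naive <- naive_window_means(vals, ann, cfg$bin_size, cfg$window_bins, lens)
  expect_equal(nrow(ws), nrow(naive))
  expect_equal(ws$n_genes, naive$n_genes)
  expect_equal(ws$mean_log2fc, naive$mean_log2fc)

  # all-zero profile -> all window means zero
  ws0 <- compute_window_means(setNames(rep(0, 90), ann$gene_id),
                              assign_bins(ann, cfg), cfg, lens)
  expect_true(all(ws0$mean_log2fc[ws0$n_genes > 0] == 0))

  # {1, -1, 0} in one window -> mean 0
  ann3 <- toy_annotation(c(1e4, 2e4, 3e4), c(1.2e4, 2.2e4, 3.2e4),
                         len = 5e5)
  v3 <- setNames(c(1, -1, 0), ann3$gene_id)
  ws3 <- compute_window_means(v3, assign_bins(ann3, cfg), cfg,
                              attr(ann3, "scaffold_lengths"))
  expect_equal(ws3$mean_log2fc[1], 0)
})

test_that("window scanner output is independent of gene input order", {
  cfg <- region_scan_config(window_bins = 4, n_perm = 100)
  set.seed(3)
  starts <- sort(sample(1:(1e6 - 3000), 50))
  ann <- toy_annotation(starts, starts + 1500, len = 1e6)
  vals <- setNames(rnorm(50), ann$gene_id)
  lens <- attr(ann, "scaffold_lengths")
  ref <- compute_window_means(vals, assign_bins(ann, cfg), cfg, lens)
  perm <- sample(50)
  shuffled_map <- assign_bins(ann[perm, ], cfg)
  got <- compute_window_means(vals[perm], shuffled_map, cfg, lens)
  expect_equal(got$mean_log2fc, ref$mean_log2fc)
})

test_that("expression strata use lower-closed quantile boundaries", {
  s <- build_strata(setNames(1:10, paste0("g", 1:10)), 5)
  expect_equal(unname(s), rep(1:5, each = 2))
  # all values equal -> a single effective stratum
  expect_message(s1 <- build_strata(rep(3, 8), 5), "tied")
  expect_equal(unique(unname(s1)), 1L)
  # stratum sizes differ by at most one for distinct values
  set.seed(2)
  s2 <- build_strata(runif(53), 5)
  expect_lte(diff(range(table(s2))), 1)
})

test_that("stratified permutation conserves the genome-wide profile mean", {
  # a single window spanning the whole scaffold: its permuted mean must
  # equal the observed genome-wide mean in every iteration (the shuffles
  # only move values between positions)
  cfg <- region_scan_config(window_bins = 10, n_perm = 200,
                            min_genes_per_window = 1, seed = 4)
  set.seed(14)
  starts <- seq(5e4, 9.5e5, by = 5e4)
  ann <- toy_annotation(starts, starts + 2000, len = 1e6)
  vals <- setNames(c(rnorm(10, 2), rnorm(9, -2)), ann$gene_id)
  strata <- setNames(rep(c(1, 2), length.out = 19), ann$gene_id)
  null <- permute_profiles(vals, strata, assign_bins(ann, cfg), cfg,
                           attr(ann, "scaffold_lengths"),
                           keep_samples = TRUE)
  expect_equal(nrow(null$observed), 1)
  expect_equal(null$observed$n_genes, 19)
  expect_equal(unname(null$samples[1, ]), rep(mean(vals), 200),
               tolerance = 1e-12)
})

test_that("tiny permutation distribution matches exhaustive enumeration", {
  # 4 genes, 2 strata of 2; window 1 holds genes 1 and 2, one per stratum:
  # its permuted mean takes each of the 4 cross combinations with prob 1/4
  cfg <- region_scan_config(window_bins = 2, n_perm = 2000,
                            min_genes_per_window = 1, seed = 6)
  ann <- toy_annotation(c(5e4, 1.5e5, 2.5e5, 3.5e5),
                        c(6e4, 1.6e5, 2.6e5, 3.6e5), len = 4e5)
  vals <- setNames(c(1, 10, 2, 20), ann$gene_id)
  strata <- setNames(c(1, 2, 1, 2), ann$gene_id)
  null <- permute_profiles(vals, strata, assign_bins(ann, cfg), cfg,
                           attr(ann, "scaffold_lengths"),
                           keep_samples = TRUE)
  m1 <- null$samples[1, ]
  expected_support <- c(5.5, 6, 10.5, 11)  # (a+b)/2, a in {1,2}, b in {10,20}
  expect_true(all(round(m1, 6) %in% expected_support))
  freq <- table(factor(round(m1, 6), levels = expected_support)) / 2000
  expect_true(all(abs(freq - 0.25) < 0.05))
})

test_that("n_perm below the quantile floor refuses to run", {
  cfg <- region_scan_config(n_perm = 100)
  cfg$n_perm <- 50L
  ann <- toy_annotation(c(5e4, 1.5e5), c(6e4, 1.6e5), len = 4e5)
  vals <- setNames(c(1, 2), ann$gene_id)
  expect_error(permute_profiles(vals, setNames(c(1, 1), ann$gene_id),
                                assign_bins(ann, cfg), cfg,
                                attr(ann, "scaffold_lengths")),
               "n_perm")
})

test_that("planted region is called; all-zero profiles are never called", {
  cfg_sim <- simulation_config(
    seed = 19,
    planted_regions = list(list(scaffold = 2, start = 1e6, end = 3e6,
                                direction = "male", effect = 2,
                                n_genes = 30)))
  ann <- generate_annotation(cfg_sim)
  sim <- generate_counts(ann, cfg_sim)
  vals <- truth_adjusted_log2fc(sim$truth, ann, 3)
  set.seed(7)
  bm <- setNames(rlnorm(nrow(ann), 3, 1.8), ann$gene_id)
  rc <- region_scan_config(n_perm = 2000, seed = 8)
  null <- permute_profiles(vals, build_strata(bm), assign_bins(ann, rc),
                           rc, attr(ann, "scaffold_lengths"))
  wc <- call_enriched_windows(null, rc)
  hits <- wc[wc$call == "male" & wc$scaffold == "scaffold_02" &
             wc$start < 3e6 & wc$end > 1e6, ]
  expect_gt(nrow(hits), 0)

  # with every adjusted log2FC zero no window can ever be called
  zero <- setNames(rep(0, nrow(ann)), ann$gene_id)
  null0 <- permute_profiles(zero, build_strata(bm), assign_bins(ann, rc),
                            rc, attr(ann, "scaffold_lengths"))
  wc0 <- call_enriched_windows(null0, rc)
  expect_equal(sum(wc0$call != "none"), 0)
})

test_that("calls at multiple window scales all overlap the planted region", {
  cfg_sim <- simulation_config(
    n_autosomes = 1, scaffold_lengths = c(5e6, 5e6), x_scaffold_index = 2,
    seed = 29,
    planted_regions = list(list(scaffold = 1, start = 1e6, end = 3e6,
                                direction = "male", effect = 2)))
  ann <- generate_annotation(cfg_sim)
  sim <- generate_counts(ann, cfg_sim)
  vals <- truth_adjusted_log2fc(sim$truth, ann, 3)
  set.seed(1)
  bm <- setNames(rlnorm(nrow(ann), 3, 1.8), ann$gene_id)
  for (wb in c(20, 10, 5)) {  # 2 Mb, 1 Mb, 500 kb
    rc <- region_scan_config(window_bins = wb, n_perm = 1000, seed = 2)
    null <- permute_profiles(vals, build_strata(bm), assign_bins(ann, rc),
                             rc, attr(ann, "scaffold_lengths"))
    wc <- call_enriched_windows(null, rc)
    hits <- wc[wc$call == "male" & wc$start < 3e6 & wc$end > 1e6, ]
    expect_gt(nrow(hits), 0)
  }
})

test_that("empirical p is stable in n_perm up to Monte-Carlo noise", {
  cfg_sim <- small_sim_config(seed = 13)
  ann <- generate_annotation(cfg_sim)
  sim <- generate_counts(ann, cfg_sim)
  vals <- truth_adjusted_log2fc(sim$truth, ann, 3)
  set.seed(5)
  bm <- setNames(rlnorm(nrow(ann), 3, 1.8), ann$gene_id)
  strata <- build_strata(bm)
  lens <- attr(ann, "scaffold_lengths")
  p_of <- function(n_perm) {
    rc <- region_scan_config(n_perm = n_perm, seed = 3,
                             min_genes_per_window = 1)
    null <- permute_profiles(vals, strata, assign_bins(ann, rc), rc, lens)
    call_enriched_windows(null, rc)$p_upper
  }
  p1 <- p_of(1000); p2 <- p_of(2000)
  tol <- 4 * sqrt(pmax(p1 * (1 - p1), 0.25 / 1000) / 1000)
  expect_true(all(abs(p1 - p2) <= tol + 2 / 1000))
})

test_that("same-direction overlapping windows merge; directions split", {
  wc <- data.frame(scaffold = c("s1", "s1", "s1", "s2"),
                   start = c(0, 1e5, 2.1e6, 0),
                   end = c(2e6, 2.1e6, 4.1e6, 2e6),
                   call = c("male", "male", "female", "male"))
  reg <- merge_regions(wc)
  expect_equal(nrow(reg), 3)
  m1 <- reg[reg$scaffold == "s1" & reg$direction == "male", ]
  expect_equal(c(m1$start, m1$end), c(0, 2.1e6))
  # adjacent but opposite-direction windows stay separate
  expect_equal(sort(reg$direction), c("female", "male", "male"))
  # no significant windows -> empty region table
  wc0 <- transform(wc, call = "none")
  expect_equal(nrow(merge_regions(wc0)), 0)
})
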