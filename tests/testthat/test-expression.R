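test_that("FPKM/TPM follow the normalization formulas", {
  counts <- matrix(c(10, 0), 1, 2,
                   dimnames = list("g1", c("s1", "s2")))
  ab <- suppressWarnings(compute_abundance(counts, c(g1 = 1000)))
  # single gene, 1 kb, count 10 of a 10-read library -> 1e6 FPKM and TPM
  expect_equal(ab$fpkm[1, "s1"], 1e6)
  expect_equal(ab$tpm[1, "s1"], 1e6)

  zero <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(ab0 <- compute_abundance(zero, c(a = 500, b = 1500)))
  expect_true(all(ab0$fpkm == 0))

  set.seed(1)
  m <- matrix(rpois(60, 40), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  lens <- setNames(c(500, 1000, 1500, 2000, 800, 3000), rownames(m))
  ab2 <- compute_abundance(m, lens)
  expect_equal(ab2$fpkm, naive_fpkm(m, lens))
  expect_equal(colSums(ab2$tpm), rep(1e6, 10), ignore_attr = TRUE)
})

test_that("expression filter applies both rules with strict inequality", {
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        sex = c("M", "M", "F", "F"), leg = 1)
  fpkm <- rbind(g_at_threshold = rep(2, 4),          # never < 2: retained
                g_zero = rep(0, 4),                  # removed
                g_half_low = c(5, 5, 1, 1),          # 2 of 4 low: retained
                g_mostly_low = c(5, 1, 1, 1),        # 3 of 4 low: removed
                g_sex_rescue = c(4, 4, 0, 0))        # male mean 4: retained
  colnames(fpkm) <- samples$sample_id
  kept <- filter_expressed(fpkm, samples, 1)
  expect_setequal(kept, c("g_at_threshold", "g_half_low", "g_sex_rescue"))
  expect_error(filter_expressed(fpkm, samples, 2), "absent")
})

test_that("rank-sum p of the DE stand-in matches exact enumeration at 3v3", {
  x <- c(1.3, 5.2, 9.1); y <- c(2.4, 7.7, 11.5)
  expect_equal(sexbiasarch:::ranksum_test(x, y)$p.value,
               exact_ranksum_p(x, y))
  x2 <- c(10, 11, 12); y2 <- c(1, 2, 3)
  expect_equal(sexbiasarch:::ranksum_test(x2, y2)$p.value,
               exact_ranksum_p(x2, y2))
})

test_that("BH adjustment equals the naive step-up oracle", {
  set.seed(7)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(sexbiasarch:::adjust_bh(p), naive_bh(p))
  }
})

test_that("DE stand-in is centred under the null and recovers planted genes", {
  set.seed(2)
  n <- 200
  counts <- matrix(rnbinom(n * 12, mu = 100, size = 20), n, 12)
  rownames(counts) <- paste0("g", seq_len(n))
  samples <- data.frame(
    sample_id = paste0("s", 1:12),
    sex = rep(c("M", "F"), each = 6),
    leg = 1, line = rep(c("big", "small"), 6),
    replicate = rep(1:3, 4))
  colnames(counts) <- samples$sample_id
  de <- run_de_standin(counts, samples, list(type = "sex", leg = 1))
  expect_lt(abs(median(de$log2FC)), 0.1)
  expect_gt(median(de$pvalue), 0.25)

  # planted genes rank among the smallest p-values; AUC > 0.9 vs truth
  cfg <- simulation_config(seed = 31)
  ann <- generate_annotation(cfg)
  sim <- generate_counts(ann, cfg)
  de3 <- run_de_standin(sim$counts, sim$samples, list(type = "sex", leg = 3))
  truth <- sim$truth$bias$leg3 != "unbiased"
  r <- rank(de3$pvalue)
  auc <- (sum(r[!truth]) - sum(!truth) * (sum(!truth) + 1) / 2) /
    (sum(truth) * sum(!truth))
  expect_gt(auc, 0.9)
})

test_that("bias calling applies the fold-change and alpha thresholds", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2FC = c(0.70, 3, -0.60, 0.2),
                   padj = c(0.01, 0.06, 0.04, 0.01))
  calls <- call_sex_bias(de, expressed = c("a", "b", "c", "d"), leg = 1)
  expect_equal(calls$label, c("male", "unbiased", "female", "unbiased"))

  # genes missing from the expressed set are unexpressed with l2fc 0, p 1
  calls2 <- call_sex_bias(de, expressed = c("a", "b"), leg = 1)
  expect_equal(calls2$label[3:4], c("unexpressed", "unexpressed"))
  expect_equal(calls2$reassigned_log2fc[3:4], c(0, 0))
  expect_equal(calls2$reassigned_p[3:4], c(1, 1))
})

test_that("log2FC reassignment zeroes unbiased genes and is idempotent", {
  de <- data.frame(gene_id = c("a", "b", "c"),
                   log2FC = c(1.2, 0.3, -2),
                   padj = c(0.001, 0.5, 0.001))
  calls <- call_sex_bias(de, expressed = c("a", "b", "c"), leg = 1)
  v <- reassign_log2fc(calls)
  expect_equal(unname(v), c(1.2, 0, -2))
  # idempotence: reassigning an already-reassigned table changes nothing
  calls$log2FC <- v[calls$gene_id]
  expect_equal(reassign_log2fc(calls), v)
})

test_that("bias summary percentages reproduce exact rounding", {
  tab <- data.frame(leg = c(1, 2, 3),
                    n_expressed = c(8950, 8706, 8710),
                    n_male = c(161, 166, 524),
                    n_female = c(398, 346, 999))
  s <- summarize_bias(tab)
  expect_equal(s$pct_male, c(1.80, 1.91, 6.02))
  expect_equal(s$pct_female, c(4.45, 3.97, 11.47))
  expect_equal(percentage(0, 100), 0)
  # percentages always recompute exactly from their own counts
  expect_equal(s$pct_male, percentage(s$n_male, s$n_expressed))
})

test_that("every gene gets exactly one label per leg", {
  cfg <- small_sim_config()
  ann <- generate_annotation(cfg)
  sim <- generate_counts(ann, cfg)
  ab <- compute_abundance(sim$counts,
                          setNames(ann$end - ann$start + 1, ann$gene_id))
  ex <- filter_expressed(ab, sim$samples, 1)
  de <- run_de_standin(sim$counts, sim$samples, list(type = "sex", leg = 1))
  calls <- call_sex_bias(de, ex, ann$gene_id, leg = 1)
  expect_equal(nrow(calls), nrow(ann))
  expect_true(all(calls$label %in% c("male", "female", "unbiased",
                                     "unexpressed")))
  s <- summarize_bias(calls)
  expect_equal(s$n_expressed, length(ex))
})

test_that("bias calling recovers planted labels with bounded error", {
  cfg <- simulation_config(seed = 61)
  ann <- generate_annotation(cfg)
  sim <- generate_counts(ann, cfg)
  ab <- compute_abundance(sim$counts,
                          setNames(ann$end - ann$start + 1, ann$gene_id))
  ex <- filter_expressed(ab, sim$samples, 3)
  de <- run_de_standin(sim$counts, sim$samples, list(type = "sex", leg = 3))
  calls <- call_sex_bias(de, ex, ann$gene_id, leg = 3)
  truth <- sim$truth$bias$leg3
  called_biased <- calls$label %in% c("male", "female")
  truly_biased <- truth %in% c("male", "female")
  fdp <- sum(called_biased & !truly_biased) / max(sum(called_biased), 1)
  sens <- sum(called_biased & truly_biased) / sum(truly_biased)
  expect_lte(fdp, 0.15)
  expect_gte(sens, 0.6)
  # direction of recovered calls matches the planted direction
  agree <- calls$label[called_biased & truly_biased] ==
    truth[called_biased & truly_biased]
  expect_gt(mean(agree), 0.99)
})

test_that("overlap cells match hand enumeration of the Venn diagram", {
  mk <- function(ids, lab = "male") {
    data.frame(gene_id = as.character(ids), label = lab)
  }
  ov <- bias_overlap(list(A = mk(1:3), B = mk(2:3), C = mk(3)), "male")
  expect_equal(ov$cells[["A"]], 1)          # {1}
  expect_equal(ov$cells[["A&B"]], 1)        # {2}
  expect_equal(ov$cells[["A&B&C"]], 1)      # {3}
  expect_equal(ov$exclusive$A, "1")
  expect_equal(length(ov$exclusive$C), 0)

  ov2 <- bias_overlap(list(leg1 = mk(c("a", "b")), leg3 = mk("c")), "male")
  expect_equal(ov2$exclusive$leg3, "c")
})

test_that("bias magnitude comparison handles ties and matches enumeration", {
  mk <- function(v) data.frame(gene_id = seq_along(v),
                               label = rep("male", length(v)),
                               log2FC = v)
  same <- mk(c(1, 1.5, 2))
  expect_equal(compare_bias_magnitude(same, same)$p.value, 1)
  a <- mk(c(0.9, 1.7, 2.8)); b <- mk(c(1.2, 2.1, 3.3))
  expect_equal(compare_bias_magnitude(a, b)$p.value,
               exact_ranksum_p(c(0.9, 1.7, 2.8), c(1.2, 2.1, 3.3)))
  expect_error(compare_bias_magnitude(a, mk(numeric())), "no male")
})

test_that("within-class PCA removes the class mean structure", {
  set.seed(4)
  n_genes <- 100
  shift <- rnorm(n_genes, 0, 2)
  x <- sapply(1:10, function(j) {
    rnorm(n_genes) + if (j <= 5) shift else 0
  })
  classes <- rep(c("lineA", "lineB"), each = 5)
  un <- within_class_pca(x, classes, correct = FALSE)
  co <- within_class_pca(x, classes, correct = TRUE)
  sep <- function(p) {
    abs(mean(p$scores[1:5, 1]) - mean(p$scores[6:10, 1])) /
      sd(p$scores[, 1])
  }
  expect_gt(sep(un), 1.5)   # uncorrected PC1 separates the lines
  expect_lt(sep(co), 1)     # corrected PC1 does not

  # single class: corrected equals ordinary PCA on centered data
  one <- within_class_pca(x, rep("only", 10), correct = TRUE)
  ref <- prcomp(t(x), center = TRUE)
  expect_equal(abs(one$scores), abs(ref$x), tolerance = 1e-8)

  # constant matrix: all variance fractions zero
  const <- within_class_pca(matrix(5, 20, 6), rep(c("a", "b"), 3))
  expect_true(all(const$var_frac == 0))
})
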