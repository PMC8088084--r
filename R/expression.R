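#' Compute FPKM and TPM abundance matrices
#'
#' FPKM = count * 1e9 / (length * column_total); TPM rescales per-kilobase
#' rates so each column sums to one million.  Effective gene length is the
#' annotated gene span in bp.
#'
#' @param counts integer matrix, genes x samples, rownames = gene ids.
#' @param gene_lengths numeric vector of effective lengths in bp, named by
#'   gene id or in row order.
#' @return list of class \code{"abundance_matrix"} with \code{fpkm},
#'   \code{tpm} and \code{gene_lengths}.
#' @export
compute_abundance <- function(counts, gene_lengths) {
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  stopifnot(length(gene_lengths) == nrow(counts), all(gene_lengths > 0),
            all(counts >= 0))
  totals <- colSums(counts)
  if (any(totals == 0)) {
    warning("zero column total: FPKM/TPM set to 0 for those samples")
  }
  safe_tot <- ifelse(totals == 0, 1, totals)
  fpkm <- sweep(counts * 1e9 / gene_lengths, 2, safe_tot, "/")
  rate <- counts / gene_lengths
  rate_tot <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(rate_tot == 0, 1, rate_tot), "/") * 1e6
  fpkm[, totals == 0] <- 0
  tpm[, totals == 0] <- 0
  structure(list(fpkm = fpkm, tpm = tpm, gene_lengths = gene_lengths),
            class = "abundance_matrix")
}

#' Expression filter configuration
#'
#' @param fpkm_threshold FPKM below which a sample counts as low (default 2).
#' @param max_low_fraction fraction of the leg's samples that may be low
#'   before the gene is discarded (default 1/2; "more than half" fails).
#' @param sex_mean_threshold a gene whose mean FPKM is below this in both
#'   sexes is discarded (default 2).
#' @return list of class \code{"expression_filter_config"}.
#' @export
expression_filter_config <- function(fpkm_threshold = 2,
                                     max_low_fraction = 0.5,
                                     sex_mean_threshold = 2) {
  stopifnot(fpkm_threshold >= 0, sex_mean_threshold >= 0)
  structure(list(fpkm_threshold = fpkm_threshold,
                 max_low_fraction = max_low_fraction,
                 sex_mean_threshold = sex_mean_threshold),
            class = "expression_filter_config")
}

#' Filter genes by expression within one leg
#'
#' A gene is retained for a leg unless (a) its FPKM is strictly below the
#' threshold in more than half of that leg's samples (lines combined), or
#' (b) its mean FPKM is strictly below the threshold in both sexes.
#'
#' @param abundance an [compute_abundance()] result (or an FPKM matrix).
#' @param samples sample sheet with \code{sample_id}, \code{sex}, \code{leg}.
#' @param leg which leg (1--3).
#' @param cfg an [expression_filter_config()].
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(abundance, samples, leg,
                             cfg = expression_filter_config()) {
  fpkm <- if (inherits(abundance, "abundance_matrix")) abundance$fpkm
          else abundance
  sel <- samples$leg == leg
  if (!any(sel)) stop("leg ", leg, " absent from design")
  sub <- fpkm[, samples$sample_id[sel], drop = FALSE]
  sexes <- samples$sex[sel]
  n <- ncol(sub)
  low <- rowSums(sub < cfg$fpkm_threshold)
  fail_low <- low > cfg$max_low_fraction * n
  mean_m <- rowMeans(sub[, sexes == "M", drop = FALSE])
  mean_f <- rowMeans(sub[, sexes == "F", drop = FALSE])
  fail_sex <- mean_m < cfg$sex_mean_threshold & mean_f < cfg$sex_mean_threshold
  rownames(sub)[!fail_low & !fail_sex]
}

# DESeq-style median-of-ratios size factors.
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  ok <- is.finite(log_geo)
  if (!any(ok)) return(stats::setNames(rep(1, ncol(counts)),
                                       colnames(counts)))
  sf <- apply(counts[ok, , drop = FALSE], 2, function(cj) {
    exp(stats::median(log(cj) - log_geo[ok]))
  })
  sf
}

#' Rank-sum differential-expression stand-in
#'
#' A deliberately simple, pluggable differential-expression stage: counts
#' are normalized by median-of-ratios size factors; the log2 fold change is
#' \code{log2((mean_A + 0.5) / (mean_B + 0.5))} on normalized group means;
#' p-values come from a two-sided rank-sum test on normalized counts and are
#' Benjamini-Hochberg adjusted within the contrast.  Downstream analyses
#' consume only (baseMean, log2FC, padj), so any externally computed
#' differential table with those columns can be supplied instead.
#'
#' For sex contrasts the two lines are pooled (the combined analysis the
#' sampling design is built for), with line recorded as a blocking label in
#' the output attributes; \code{per_line} restricts to one line.
#'
#' @param counts genes x samples count matrix.
#' @param samples sample sheet.
#' @param contrast list: either \code{list(type = "sex", leg = L)} (A = male,
#'   B = female within leg L, positive log2FC = male-biased) or
#'   \code{list(type = "leg", sex = S, legs = c(3, 1))} (A = first element,
#'   positive log2FC = leg-3-biased by default).
#' @param per_line optional line label to restrict the sex contrast to.
#' @return \code{data.frame} with \code{gene_id}, \code{contrast},
#'   \code{baseMean}, \code{log2FC}, \code{pvalue}, \code{padj}.
#' @export
run_de_standin <- function(counts, samples, contrast, per_line = NULL) {
  if (!is.null(per_line)) {
    keep <- samples$line == per_line
    samples <- samples[keep, , drop = FALSE]
    counts <- counts[, samples$sample_id, drop = FALSE]
  }
  if (contrast$type == "sex") {
    in_leg <- samples$leg == contrast$leg
    a <- samples$sample_id[in_leg & samples$sex == "M"]
    b <- samples$sample_id[in_leg & samples$sex == "F"]
    label <- sprintf("sex_leg%d%s", contrast$leg,
                     if (is.null(per_line)) "" else paste0("_", per_line))
  } else if (contrast$type == "leg") {
    legs <- contrast$legs %||% c(3, 1)
    in_sex <- samples$sex == contrast$sex
    a <- samples$sample_id[in_sex & samples$leg == legs[1]]
    b <- samples$sample_id[in_sex & samples$leg == legs[2]]
    label <- sprintf("leg%dv%d_%s", legs[1], legs[2], contrast$sex)
  } else {
    stop("unknown contrast type: ", contrast$type)
  }
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 samples per group")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  na <- norm[, a, drop = FALSE]
  nb <- norm[, b, drop = FALSE]
  mean_a <- rowMeans(na)
  mean_b <- rowMeans(nb)
  base_mean <- rowMeans(norm[, c(a, b), drop = FALSE])
  l2fc <- log2((mean_a + 0.5) / (mean_b + 0.5))
  p <- vapply(seq_len(nrow(norm)), function(i) {
    if (all(na[i, ] == 0) && all(nb[i, ] == 0)) return(1)
    ranksum_test(na[i, ], nb[i, ])$p.value
  }, numeric(1))
  l2fc[mean_a == 0 & mean_b == 0] <- 0
  out <- data.frame(gene_id = rownames(counts), contrast = label,
                    baseMean = base_mean, log2FC = l2fc,
                    pvalue = p, padj = adjust_bh(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "blocking") <- if (contrast$type == "sex" && is.null(per_line)) {
    "line"
  } else {
    "none"
  }
  out
}

#' Bias-call configuration
#'
#' @param fc_threshold linear fold-change threshold (default 1.5; a gene is
#'   biased when |log2FC| > log2(1.5)).
#' @param alpha adjusted-p cutoff (default 0.05, strict).
#' @return list of class \code{"bias_call_config"}.
#' @export
bias_call_config <- function(fc_threshold = 1.5, alpha = 0.05) {
  stopifnot(fc_threshold > 1, alpha > 0, alpha < 1)
  structure(list(fc_threshold = fc_threshold, alpha = alpha),
            class = "bias_call_config")
}

#' Call per-gene sex bias for one leg
#'
#' Labels each gene of the universe: \code{male} when log2FC > log2(1.5) and
#' padj < 0.05, \code{female} when log2FC < -log2(1.5) and padj < 0.05,
#' \code{unbiased} otherwise, and \code{unexpressed} for genes that failed
#' the expression filter.  The reassigned log2FC keeps the original value
#' only for biased genes; unbiased genes get 0 and unexpressed genes get 0
#' with p = 1, the substrate of the window scan.
#'
#' @param de differential table (\code{gene_id}, \code{log2FC}, \code{padj}).
#' @param expressed character vector of expressed gene ids for this leg.
#' @param universe all gene ids to label (default: genes in \code{de}).
#' @param leg leg index recorded in the output.
#' @param cfg a [bias_call_config()].
#' @return \code{data.frame} of class \code{"bias_calls"}: \code{gene_id},
#'   \code{leg}, \code{label}, \code{log2FC}, \code{padj},
#'   \code{reassigned_log2fc}, \code{reassigned_p}.
#' @export
call_sex_bias <- function(de, expressed, universe = de$gene_id, leg = NA,
                          cfg = bias_call_config()) {
  idx <- match(universe, de$gene_id)
  l2fc <- de$log2FC[idx]
  padj <- de$padj[idx]
  if (anyNA(padj[!is.na(idx)])) {
    message("missing padj treated as 1")
  }
  padj[is.na(padj)] <- 1
  l2fc[is.na(l2fc)] <- 0
  thr <- log2(cfg$fc_threshold)
  label <- ifelse(l2fc > thr & padj < cfg$alpha, "male",
           ifelse(l2fc < -thr & padj < cfg$alpha, "female", "unbiased"))
  label[!(universe %in% expressed)] <- "unexpressed"
  out <- data.frame(gene_id = universe, leg = leg, label = label,
                    log2FC = ifelse(label == "unexpressed", 0, l2fc),
                    padj = ifelse(label == "unexpressed", 1, padj),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$reassigned_log2fc <- ifelse(out$label %in% c("male", "female"),
                                  out$log2FC, 0)
  out$reassigned_p <- ifelse(out$label == "unexpressed", 1, out$padj)
  class(out) <- c("bias_calls", "data.frame")
  out
}

#' Reassigned log2 fold-change vector
#'
#' Extracts the adjusted per-gene log2FC from a bias-call table: 0 for
#' unexpressed and unbiased genes, the original log2FC for biased genes.
#' Idempotent by construction.
#'
#' @param calls a [call_sex_bias()] table.
#' @return named numeric vector over \code{calls$gene_id}.
#' @export
reassign_log2fc <- function(calls) {
  stats::setNames(ifelse(calls$label %in% c("male", "female"),
                         calls$log2FC, 0),
                  calls$gene_id)
}

#' Summarize bias calls per leg
#'
#' Produces the per-leg table of expressed, male- and female-biased gene
#' counts with percentages of expressed genes, rounded half away from zero
#' to two decimals.  Accepts either a bias-call table (column \code{label})
#' or a precomputed count table with columns \code{leg}, \code{n_expressed},
#' \code{n_male}, \code{n_female}, in which case only the percentages are
#' (re)computed -- useful for checking published count tables.
#'
#' @param x bias calls (possibly several legs row-bound) or a count table.
#' @return \code{data.frame}: \code{leg}, \code{n_expressed}, \code{n_male},
#'   \code{pct_male}, \code{n_female}, \code{pct_female}.
#' @export
summarize_bias <- function(x) {
  if ("label" %in% names(x)) {
    legs <- sort(unique(x$leg))
    x <- do.call(rbind, lapply(legs, function(lg) {
      sub <- x[x$leg == lg, ]
      data.frame(leg = lg,
                 n_expressed = sum(sub$label != "unexpressed"),
                 n_male = sum(sub$label == "male"),
                 n_female = sum(sub$label == "female"))
    }))
  }
  stopifnot(all(c("leg", "n_expressed", "n_male", "n_female") %in% names(x)))
  data.frame(leg = x$leg, n_expressed = x$n_expressed,
             n_male = x$n_male,
             pct_male = percentage(x$n_male, x$n_expressed),
             n_female = x$n_female,
             pct_female = percentage(x$n_female, x$n_expressed),
             row.names = NULL)
}

#' Overlap structure of biased gene sets across legs
#'
#' Set algebra over the per-leg biased gene sets of one direction: every
#' intersection cell of the Venn diagram plus per-leg exclusive sets.
#'
#' @param calls_list named list of bias-call tables (one per leg).
#' @param direction "male" or "female".
#' @return list with \code{sets} (the input sets), \code{cells} (named
#'   counts of all non-empty membership patterns, names like "leg1&leg3"),
#'   and \code{exclusive} (per-leg exclusive gene ids).
#' @export
bias_overlap <- function(calls_list, direction = "male") {
  sets <- lapply(calls_list, function(cl) cl$gene_id[cl$label == direction])
  nm <- names(sets) %||% paste0("set", seq_along(sets))
  names(sets) <- nm
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(row) paste(nm[row], collapse = "&"))
  cells <- table(pattern)
  exclusive <- lapply(seq_along(sets), function(i) {
    setdiff(sets[[i]], unlist(sets[-i]))
  })
  names(exclusive) <- nm
  list(sets = sets, cells = as.list(cells), exclusive = exclusive)
}

#' Compare bias magnitudes between two legs
#'
#' Two-sided rank-sum test on |log2FC| of the direction-matched biased genes
#' of two legs.
#'
#' @param calls_a,calls_b bias-call tables for the two legs.
#' @param direction "male" or "female".
#' @return list with \code{statistic}, \code{p.value}, \code{n} (per side),
#'   \code{median_abs_l2fc} (per side).
#' @export
compare_bias_magnitude <- function(calls_a, calls_b, direction = "male") {
  xa <- abs(calls_a$log2FC[calls_a$label == direction])
  xb <- abs(calls_b$log2FC[calls_b$label == direction])
  if (!length(xa) || !length(xb)) stop("no ", direction,
                                       "-biased genes on one side")
  rs <- ranksum_test(xa, xb)
  list(statistic = rs$statistic, p.value = rs$p.value,
       n = c(length(xa), length(xb)),
       median_abs_l2fc = c(stats::median(xa), stats::median(xb)))
}

#' Principal component analysis with within-class correction
#'
#' Ordinary PCA of the samples, optionally after removing class means
#' (here: inbred line) from each sample, so that axes of variation due to
#' the class factor are suppressed and the remaining factors (sex, leg)
#' dominate the leading components.
#'
#' @param log_expr matrix genes x samples (e.g. log2(TPM + 1)).
#' @param classes factor/character of length ncol(log_expr); class of each
#'   sample.
#' @param correct if TRUE remove class means before the PCA.
#' @return list of class \code{"pca_result"}: \code{scores} (samples x
#'   components), \code{var_frac}, \code{corrected}.
#' @export
within_class_pca <- function(log_expr, classes, correct = TRUE) {
  x <- t(log_expr)
  if (correct) {
    stopifnot(length(classes) == nrow(x))
    if (min(table(classes)) < 2 && length(unique(classes)) > 1) {
      stop("corrected mode needs >= 2 samples per class")
    }
    for (cl in unique(classes)) {
      sel <- classes == cl
      x[sel, ] <- sweep(x[sel, , drop = FALSE], 2,
                        colMeans(x[sel, , drop = FALSE]))
    }
  }
  total_var <- sum(apply(x, 2, stats::var))
  if (!is.finite(total_var) || total_var == 0) {
    k <- min(dim(x))
    return(structure(list(scores = matrix(0, nrow(x), k,
                                          dimnames = list(rownames(x), NULL)),
                          var_frac = rep(0, k), corrected = correct),
                     class = "pca_result"))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  structure(list(scores = pc$x, var_frac = pc$sdev^2 / sum(pc$sdev^2),
                 corrected = correct),
            class = "pca_result")
}
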