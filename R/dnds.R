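#' Compare dN/dS between two gene categories
#'
#' Two-sided rank-sum (Wilcoxon) test on the dN/dS ratios of two gene
#' categories on one branch.  Genes with dS = 0 have no defined ratio and
#' are excluded, with the exclusion count reported.
#'
#' @param records dN/dS table: \code{gene_id}, \code{species}, \code{dN},
#'   \code{dS} (a \code{ratio} column is recomputed if absent).
#' @param labels named character vector of category labels per gene id.
#' @param pair the two categories compared, first vs second (default
#'   male-biased vs unbiased).
#' @param species branch to use (default: all rows; pass a label to
#'   restrict).
#' @return list of class \code{"dnds_comparison"}: \code{statistic},
#'   \code{p.value}, \code{medians} (named), \code{n} (named),
#'   \code{n_excluded}.
#' @export
compare_dnds <- function(records, labels, pair = c("male", "unbiased"),
                         species = NULL) {
  if (!is.null(species)) {
    records <- records[records$species == species, , drop = FALSE]
  }
  stopifnot(all(records$dN >= 0), all(records$dS >= 0))
  ratio <- ifelse(records$dS > 0, records$dN / records$dS, NA_real_)
  lab <- labels[records$gene_id]
  n_excluded <- sum(is.na(ratio) & lab %in% pair)
  x <- ratio[lab == pair[1] & !is.na(ratio)]
  y <- ratio[lab == pair[2] & !is.na(ratio)]
  if (length(x) < 2 || length(y) < 2) {
    stop("need >= 2 genes with defined dN/dS in each category")
  }
  rs <- ranksum_test(x, y)
  structure(list(statistic = rs$statistic, p.value = rs$p.value,
                 medians = stats::setNames(c(stats::median(x),
                                             stats::median(y)), pair),
                 n = stats::setNames(c(length(x), length(y)), pair),
                 n_excluded = n_excluded),
            class = "dnds_comparison")
}

#' Bootstrap configuration for the dN/dS label permutation
#'
#' @param n_male genes drawn as "male-biased" per iteration (default 253).
#' @param n_female genes drawn as "female-biased" (default 463).
#' @param n_iter iterations (default 1000).
#' @param quantile fraction of bootstrap p-values required to exceed the
#'   cutoff (default 0.9995).
#' @param seed RNG seed.
#' @return list of class \code{"dnds_bootstrap_config"}.
#' @export
dnds_bootstrap_config <- function(n_male = 253, n_female = 463,
                                  n_iter = 1000, quantile = 0.9995,
                                  seed = 1L) {
  stopifnot(n_iter >= 100, quantile > 0.5, quantile < 1)
  structure(list(n_male = as.integer(n_male),
                 n_female = as.integer(n_female),
                 n_iter = as.integer(n_iter), quantile = quantile,
                 seed = as.integer(seed)),
            class = "dnds_bootstrap_config")
}

#' Label-permutation bootstrap for the dN/dS category tests
#'
#' Guards the observed male-biased vs unbiased (and female vs unbiased)
#' rank-sum p-value against chance labelling: each iteration sets every
#' gene unbiased, draws \code{n_male} "male" and \code{n_female} "female"
#' labels without replacement, and recomputes both comparisons.  The
#' empirical cutoff is the p-value below which only a fraction
#' \code{1 - quantile} (default 0.05\%) of bootstrap p-values fall; an
#' observed p-value below the cutoff is unlikely to arise from random
#' labelling.
#'
#' @param records dN/dS table as in [compare_dnds()].
#' @param cfg a [dnds_bootstrap_config()].
#' @param species optional branch restriction.
#' @return list of class \code{"dnds_bootstrap"}: \code{p_male},
#'   \code{p_female} (bootstrap p-value vectors), \code{cutoff_male},
#'   \code{cutoff_female}, \code{cfg}.
#' @export
label_bootstrap <- function(records, cfg = dnds_bootstrap_config(),
                            species = NULL) {
  if (!is.null(species)) {
    records <- records[records$species == species, , drop = FALSE]
  }
  ratio <- ifelse(records$dS > 0, records$dN / records$dS, NA_real_)
  ids <- records$gene_id[!is.na(ratio)]
  vals <- ratio[!is.na(ratio)]
  n <- length(vals)
  if (cfg$n_male + cfg$n_female > n) {
    stop("not enough genes with defined dN/dS for the label draw")
  }
  p_male <- p_female <- numeric(cfg$n_iter)
  with_seed(derive_seed(cfg$seed, 31L), {
    for (it in seq_len(cfg$n_iter)) {
      drawn <- sample.int(n, cfg$n_male + cfg$n_female)
      m <- drawn[seq_len(cfg$n_male)]
      f <- drawn[cfg$n_male + seq_len(cfg$n_female)]
      u <- setdiff(seq_len(n), drawn)
      p_male[it] <- ranksum_test(vals[m], vals[u])$p.value
      p_female[it] <- ranksum_test(vals[f], vals[u])$p.value
    }
  })
  lo <- 1 - cfg$quantile
  structure(list(p_male = p_male, p_female = p_female,
                 cutoff_male = stats::quantile(p_male, lo, type = 1,
                                               names = FALSE),
                 cutoff_female = stats::quantile(p_female, lo, type = 1,
                                                 names = FALSE),
                 n_genes = n, cfg = cfg),
            class = "dnds_bootstrap")
}

#' Declare an observed p-value (non-)random against the bootstrap
#'
#' @param observed_p observed comparison p-value.
#' @param bootstrap a [label_bootstrap()] result.
#' @param direction "male" or "female".
#' @return list: \code{observed_p}, \code{cutoff}, \code{non_random}
#'   (TRUE when observed_p < cutoff).
#' @export
assess_bootstrap <- function(observed_p, bootstrap, direction = "male") {
  cutoff <- if (direction == "male") bootstrap$cutoff_male
            else bootstrap$cutoff_female
  list(observed_p = observed_p, cutoff = cutoff,
       non_random = observed_p < cutoff)
}

#' Cross-classify sex-bias and leg-bias labels
#'
#' Four-way categories (sex-bias x leg-bias) over a shared gene universe,
#' for testing which combination carries a dN/dS signal.  Empty categories
#' are flagged so downstream comparisons can skip them.
#'
#' @param sex_labels named vector with values in {male, female, unbiased}.
#' @param leg_labels named vector with values in {leg-biased vocabularies};
#'   anything other than "none"/"unbiased" counts as leg-biased.
#' @return list: \code{labels} (named vector like "male/leg-biased"),
#'   \code{table} (category counts), \code{empty} (names of empty
#'   categories among the 6 sex x leg combinations).
#' @export
stratify_by_leg_bias <- function(sex_labels, leg_labels) {
  ids <- intersect(names(sex_labels), names(leg_labels))
  if (!setequal(names(sex_labels), names(leg_labels))) {
    stop("sex and leg label sets are on different gene universes")
  }
  legb <- ifelse(leg_labels[ids] %in% c("none", "unbiased", NA),
                 "leg-unbiased", "leg-biased")
  combined <- paste(sex_labels[ids], legb, sep = "/")
  names(combined) <- ids
  all_cats <- as.vector(outer(c("male", "female", "unbiased"),
                              c("leg-biased", "leg-unbiased"), paste,
                              sep = "/"))
  tab <- table(factor(combined, levels = all_cats))
  list(labels = combined, table = tab,
       empty = names(tab)[tab == 0])
}
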