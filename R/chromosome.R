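#' Identify the X chromosome from male genomic coverage
#'
#' Among the \code{top_n} largest scaffolds, the X is the unique scaffold
#' whose male read depth is about half the depth of the others (males are
#' hemizygous for the X).  "About half" is operationalized as a depth ratio
#' to the median of the other scaffolds inside \code{band} (default
#' [0.35, 0.65], robust to Poisson depth noise).  No or multiple candidates
#' leave the X unassigned, with per-scaffold diagnostics returned.
#'
#' @param coverage \code{data.frame} with \code{scaffold_id}, \code{length},
#'   \code{mean_depth} (male-only genomic coverage).
#' @param top_n how many of the largest scaffolds to consider (default 13).
#' @param band acceptance interval for the depth ratio.
#' @return list of class \code{"x_assignment"}: \code{x_scaffold_id} (or
#'   NA), \code{ratio}, \code{diagnostics} (ratio per candidate scaffold).
#' @export
identify_x <- function(coverage, top_n = 13, band = c(0.35, 0.65)) {
  if (!nrow(coverage)) stop("empty coverage table")
  if (nrow(coverage) < 2) stop("need >= 2 scaffolds")
  top <- coverage[order(-coverage$length), , drop = FALSE]
  top <- utils::head(top, top_n)
  ratio <- vapply(seq_len(nrow(top)), function(i) {
    top$mean_depth[i] / stats::median(top$mean_depth[-i])
  }, numeric(1))
  diag <- data.frame(scaffold_id = top$scaffold_id, length = top$length,
                     mean_depth = top$mean_depth, ratio = ratio,
                     stringsAsFactors = FALSE)
  hit <- which(ratio >= band[1] & ratio <= band[2])
  res <- list(x_scaffold_id = NA_character_, ratio = NA_real_,
              diagnostics = diag)
  if (length(hit) == 1L) {
    res$x_scaffold_id <- top$scaffold_id[hit]
    res$ratio <- ratio[hit]
  }
  class(res) <- "x_assignment"
  res
}

#' Scan for Y-chromosome candidate scaffolds
#'
#' Flags scaffolds (among the \code{top_n} largest, excluding the X) whose
#' coverage ratio is X-like -- consistent with a single copy in males --
#' and whose expressed genes are exclusively male-biased.  A true X shows
#' both male- and female-biased genes and is thereby excluded.
#'
#' @param coverage coverage table as in [identify_x()].
#' @param calls bias-call table(s), possibly several legs row-bound.
#' @param annotation gene annotation.
#' @param x_id assigned X scaffold id.
#' @param top_n scaffolds to scan (default 50).
#' @param band X-like coverage-ratio interval.
#' @return character vector of candidate scaffold ids (possibly empty).
#' @export
scan_y_candidates <- function(coverage, calls, annotation, x_id,
                              top_n = 50, band = c(0.35, 0.65)) {
  top <- coverage[order(-coverage$length), , drop = FALSE]
  top <- utils::head(top, top_n)
  auto_depth <- stats::median(top$mean_depth[top$scaffold_id != x_id])
  ratio <- top$mean_depth / auto_depth
  xlike <- top$scaffold_id[ratio >= band[1] & ratio <= band[2] &
                           top$scaffold_id != x_id]
  expressed <- calls[calls$label != "unexpressed", , drop = FALSE]
  scaf_of <- annotation$scaffold[match(expressed$gene_id,
                                       annotation$gene_id)]
  Filter(function(s) {
    labs <- expressed$label[scaf_of == s & !is.na(scaf_of)]
    length(labs) > 0 && all(labs == "male")
  }, xlike)
}

#' Test dosage compensation on the X chromosome
#'
#' For each leg, keeps X-linked genes with FPKM > threshold in at least half
#' of the leg's samples, averages each gene's FPKM over replicates and lines
#' within each sex, and compares male versus female per-gene log2 mean FPKM
#' with a two-sided rank-sum test.  Under full compensation the test is a
#' null; uncompensated X expression shows up as a male down-shift.
#'
#' @param abundance [compute_abundance()] result or FPKM matrix.
#' @param annotation gene annotation.
#' @param x_id X scaffold id.
#' @param samples sample sheet.
#' @param legs legs to test (default 1:3).
#' @param fpkm_threshold expression threshold (default 2).
#' @return \code{data.frame}: \code{leg}, \code{n_genes},
#'   \code{median_log2_male}, \code{median_log2_female}, \code{statistic},
#'   \code{p.value}.
#' @export
test_dosage_compensation <- function(abundance, annotation, x_id, samples,
                                     legs = 1:3, fpkm_threshold = 2) {
  fpkm <- if (inherits(abundance, "abundance_matrix")) abundance$fpkm
          else abundance
  x_genes <- annotation$gene_id[annotation$scaffold == x_id]
  x_genes <- intersect(x_genes, rownames(fpkm))
  out <- lapply(legs, function(lg) {
    sel <- samples$leg == lg
    sub <- fpkm[x_genes, samples$sample_id[sel], drop = FALSE]
    keep <- rowSums(sub > fpkm_threshold) >= ncol(sub) / 2
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) < 5) {
      warning("fewer than 5 expressed X genes in leg ", lg)
    }
    sexes <- samples$sex[sel]
    m <- log2(rowMeans(sub[, sexes == "M", drop = FALSE]))
    f <- log2(rowMeans(sub[, sexes == "F", drop = FALSE]))
    rs <- if (nrow(sub)) ranksum_test(m, f) else list(statistic = NA,
                                                      p.value = NA)
    data.frame(leg = lg, n_genes = nrow(sub),
               median_log2_male = stats::median(m),
               median_log2_female = stats::median(f),
               statistic = rs$statistic, p.value = rs$p.value)
  })
  do.call(rbind, out)
}

#' Fisher test of sex-biased gene enrichment on the X
#'
#' Builds the 2x2 table {direction-biased, not} x {X, autosome} over one
#' leg's expressed genes on the 13 largest scaffolds (the X plus the 12
#' largest others) and applies a two-sided Fisher exact test
#' (point-probability method; the odds ratio is the conditional MLE).
#'
#' @param calls bias-call table for the leg.
#' @param annotation gene annotation.
#' @param x_id X scaffold id.
#' @param direction "male" or "female".
#' @param scaffold_lengths named lengths; default from the annotation
#'   attribute, else the max gene end per scaffold.
#' @param n_autosomes autosomes kept in the universe (default 12 largest).
#' @param universe "expressed" (default) or "annotated".
#' @return list of class \code{"fisher_result"}: \code{table},
#'   \code{odds_ratio}, \code{p.value}, \code{direction_label},
#'   \code{or_infinite}.
#' @export
fisher_x_enrichment <- function(calls, annotation, x_id,
                                direction = "female",
                                scaffold_lengths = NULL,
                                n_autosomes = 12,
                                universe = c("expressed", "annotated")) {
  universe <- match.arg(universe)
  lens <- scaffold_lengths %||% attr(annotation, "scaffold_lengths") %||%
    tapply(annotation$end, annotation$scaffold, max)
  autos <- names(sort(lens[names(lens) != x_id], decreasing = TRUE))
  autos <- utils::head(autos, n_autosomes)
  keep_scaf <- c(x_id, autos)
  scaf <- annotation$scaffold[match(calls$gene_id, annotation$gene_id)]
  sub <- calls[scaf %in% keep_scaf, , drop = FALSE]
  scaf <- scaf[scaf %in% keep_scaf]
  if (universe == "expressed") {
    keep <- sub$label != "unexpressed"
    sub <- sub[keep, , drop = FALSE]
    scaf <- scaf[keep]
  }
  on_x <- scaf == x_id
  biased <- sub$label == direction
  tab <- matrix(c(sum(biased & on_x), sum(biased & !on_x),
                  sum(!biased & on_x), sum(!biased & !on_x)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("biased", "not_biased"),
                                c("X", "autosome")))
  fisher_2x2(tab, direction)
}

# Shared Fisher wrapper: degenerate margins give p = 1 and an undefined OR.
fisher_2x2 <- function(tab, direction_label_for = "biased") {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    res <- list(table = tab, odds_ratio = NA_real_, p.value = 1,
                direction_label = "undefined", or_infinite = FALSE)
    class(res) <- "fisher_result"
    return(res)
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or <- unname(ft$estimate)
  res <- list(table = tab, odds_ratio = or, p.value = ft$p.value,
              direction_label = if (or > 1) "enriched" else if (or < 1)
                "depleted" else "none",
              or_infinite = !is.finite(or))
  class(res) <- "fisher_result"
  res
}

#' Crosstalk between sex-biased and leg-biased regulation
#'
#' Tests whether the genes sex-biased in one leg are enriched among the
#' genes leg-biased within one sex, over the shared expressed universe:
#' 2x2 = {sex-biased, not} x {leg-biased, not}, Fisher exact, plus the
#' overlap count and its percentage of the sex-biased set (2 decimals).
#'
#' @param sex_calls bias-call table (sex contrast, one leg).
#' @param leg_calls bias-call table from a leg contrast within one sex; its
#'   \code{label} column must use the same vocabulary, with "male" meaning
#'   up in the first contrast level (e.g. leg-3-biased).
#' @param sex_direction direction of sex bias tested (default "male").
#' @param leg_direction direction of leg bias tested (default "male", i.e.
#'   up in leg 3 when the contrast is leg3 vs leg1).
#' @return list of class \code{"crosstalk_result"}: \code{overlap},
#'   \code{n_sex_biased}, \code{fraction_pct}, \code{fisher}
#'   (a \code{"fisher_result"}).
#' @export
crosstalk_enrichment <- function(sex_calls, leg_calls,
                                 sex_direction = "male",
                                 leg_direction = "male") {
  if (!setequal(sex_calls$gene_id, leg_calls$gene_id)) {
    stop("sex and leg call sets are on different gene universes")
  }
  leg_calls <- leg_calls[match(sex_calls$gene_id, leg_calls$gene_id), ,
                         drop = FALSE]
  expressed <- sex_calls$label != "unexpressed" &
    leg_calls$label != "unexpressed"
  s <- sex_calls$label[expressed] == sex_direction
  l <- leg_calls$label[expressed] == leg_direction
  tab <- matrix(c(sum(s & l), sum(s & !l), sum(!s & l), sum(!s & !l)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("sex_biased", "not"),
                                c("leg_biased", "not")))
  res <- list(overlap = sum(s & l), n_sex_biased = sum(s),
              fraction_pct = percentage(sum(s & l), sum(s)),
              fisher = fisher_2x2(tab))
  class(res) <- "crosstalk_result"
  res
}
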