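#' Gene order with bias labels
#'
#' Orders genes along each scaffold by start coordinate and attaches the
#' per-gene bias label, collapsing everything that is not male- or
#' female-biased to "unbiased".  Scaffolds are processed independently so
#' runs can never span a scaffold boundary.
#'
#' @param annotation gene annotation.
#' @param calls bias-call table for one leg.
#' @param scaffolds optional scaffold ids to keep (e.g. the 13 largest);
#'   default all.
#' @return \code{data.frame} of class \code{"gene_order"}: \code{scaffold},
#'   \code{gene_id}, \code{label}, sorted by (scaffold, start).
#' @export
gene_order <- function(annotation, calls, scaffolds = NULL) {
  ann <- annotation[order(annotation$scaffold, annotation$start), ,
                    drop = FALSE]
  if (!is.null(scaffolds)) ann <- ann[ann$scaffold %in% scaffolds, ,
                                      drop = FALSE]
  lab <- calls$label[match(ann$gene_id, calls$gene_id)]
  lab[is.na(lab) | !(lab %in% c("male", "female"))] <- "unbiased"
  out <- data.frame(scaffold = ann$scaffold, gene_id = ann$gene_id,
                    label = lab, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gene_order", "data.frame")
  out
}

#' Find runs of consecutive same-direction sex-biased genes
#'
#' Maximal runs of >= 2 adjacent genes with the same biased label along the
#' gene order of each scaffold.  Any unbiased gene, or a biased gene of the
#' opposite direction, breaks a run; runs never join across scaffolds.
#'
#' @param order a [gene_order()] table (or any data.frame with
#'   \code{scaffold}, \code{gene_id}, \code{label}).
#' @return \code{data.frame} of class \code{"cluster_records"}:
#'   \code{scaffold}, \code{first_index} (gene rank within the scaffold),
#'   \code{size}, \code{direction}, \code{gene_ids} (comma-separated).
#' @export
find_clusters <- function(order) {
  res <- list()
  for (s in unique(order$scaffold)) {
    lab <- order$label[order$scaffold == s]
    ids <- order$gene_id[order$scaffold == s]
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values %in% c("male", "female") & r$lengths >= 2
    if (any(keep)) {
      res[[s]] <- data.frame(
        scaffold = s, first_index = starts[keep], size = r$lengths[keep],
        direction = r$values[keep],
        gene_ids = vapply(which(keep), function(i) {
          paste(ids[starts[i]:ends[i]], collapse = ",")
        }, character(1)),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(scaffold = character(), first_index = integer(),
               size = integer(), direction = character(),
               gene_ids = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("cluster_records", "data.frame")
  out
}

#' Summarize cluster content per direction
#'
#' Clustered proportion = (number of biased genes inside clusters of that
#' direction) / (total biased genes of that direction), plus a histogram of
#' cluster sizes.
#'
#' @param records a [find_clusters()] table.
#' @param label_counts named counts of biased genes,
#'   \code{c(male = ..., female = ...)}.
#' @return list of class \code{"cluster_summary"}: \code{proportion}
#'   (named, NA when the direction has zero biased genes),
#'   \code{size_hist} (\code{data.frame} direction/size/n_clusters),
#'   \code{label_counts}.
#' @export
cluster_summary <- function(records, label_counts) {
  dirs <- c("male", "female")
  prop <- vapply(dirs, function(d) {
    tot <- label_counts[[d]] %||% 0
    if (is.na(tot) || tot == 0) return(NA_real_)
    sum(records$size[records$direction == d]) / tot
  }, numeric(1))
  hist <- if (nrow(records)) {
    as.data.frame(table(direction = records$direction, size = records$size),
                  responseName = "n_clusters")
  } else {
    data.frame(direction = character(), size = character(),
               n_clusters = integer())
  }
  hist <- hist[hist$n_clusters > 0, , drop = FALSE]
  hist$size <- as.integer(as.character(hist$size))
  rownames(hist) <- NULL
  structure(list(proportion = prop, size_hist = hist,
                 label_counts = unlist(label_counts)),
            class = "cluster_summary")
}

# Run sizes (>= 2) per direction from a label vector with scaffold breaks.
# Equivalent to find_clusters() on the same order but without building any
# per-cluster records; used in the permutation loop.  `slots`, `break_idx`
# and `keep_idx` are precomputed by cluster_null() so each iteration only
# fills the template and runs one rle over the whole genome.
run_sizes <- function(template, keep_idx, labels, male = "male",
                      female = "female") {
  template[keep_idx] <- labels
  r <- rle(template)
  keep <- r$lengths >= 2 & (r$values == male | r$values == female)
  list(male = r$lengths[keep & r$values == male],
       female = r$lengths[keep & r$values == female])
}

#' Permutation null for the cluster statistics
#'
#' Each iteration assigns the observed label multiset to random genomic
#' positions (a genome-wide shuffle over the concatenated gene order of all
#' scaffolds, preserving each scaffold's gene count; per-scaffold shuffling
#' available) and recomputes the clustered proportions and size histogram.
#' Reported are means and central 95\% fluctuation intervals over the
#' iterations.
#'
#' @param order a [gene_order()] table carrying the observed labels.
#' @param n_iter iterations (default 1000).
#' @param interval central interval mass (default 0.95).
#' @param per_scaffold shuffle within each scaffold instead of genome-wide.
#' @param seed RNG seed.
#' @return list of class \code{"cluster_null"}: \code{mean_proportion},
#'   \code{interval} (2 x directions), \code{size_counts} (mean and
#'   interval of the number of clusters per size class), \code{n_iter},
#'   \code{label_counts}, \code{seed}.
#' @export
cluster_null <- function(order, n_iter = 1000, interval = 0.95,
                         per_scaffold = FALSE, seed = 1L) {
  if (n_iter < 100) stop("n_iter must be >= 100")
  label_counts <- list(male = sum(order$label == "male"),
                       female = sum(order$label == "female"))
  lo <- (1 - interval) / 2
  probs <- c(lo, 1 - lo)
  dirs <- c("male", "female")
  prop_mat <- matrix(NA_real_, n_iter, 2, dimnames = list(NULL, dirs))
  size_tabs <- vector("list", n_iter)
  # genome template with a scaffold-break sentinel between scaffolds so a
  # single rle never joins runs across scaffolds
  sc_len <- rle(as.character(order$scaffold))$lengths
  n <- nrow(order)
  total <- n + length(sc_len)
  break_idx <- cumsum(sc_len + 1L)
  keep_idx <- setdiff(seq_len(total), break_idx)
  # integer label encoding keeps the rle and shuffles cheap
  lab_int <- match(order$label, c("male", "female"))
  lab_int[is.na(lab_int)] <- 0L
  template <- integer(total)
  template[break_idx] <- -1L
  scaffold_grp <- if (per_scaffold) {
    rep(seq_along(sc_len), sc_len)
  }
  with_seed(derive_seed(seed, 21L), {
    for (it in seq_len(n_iter)) {
      labs <- if (per_scaffold) {
        unlist(lapply(split(lab_int, scaffold_grp), sample),
               use.names = FALSE)
      } else {
        sample(lab_int)
      }
      rs <- run_sizes(template, keep_idx, labs, male = 1L, female = 2L)
      prop_mat[it, 1] <- if (label_counts$male > 0) {
        sum(rs$male) / label_counts$male
      } else {
        NA_real_
      }
      prop_mat[it, 2] <- if (label_counts$female > 0) {
        sum(rs$female) / label_counts$female
      } else {
        NA_real_
      }
      size_tabs[[it]] <- rs
    }
  })
  sizes <- sort(unique(unlist(size_tabs)))
  if (!length(sizes)) {
    size_counts <- data.frame(direction = character(), size = integer(),
                              mean = numeric(), lower = numeric(),
                              upper = numeric())
  } else {
  size_counts <- do.call(rbind, lapply(dirs, function(d) {
    do.call(rbind, lapply(sizes, function(sz) {
      cnt <- vapply(size_tabs, function(h) sum(h[[d]] == sz), numeric(1))
      data.frame(direction = d, size = sz, mean = mean(cnt),
                 lower = stats::quantile(cnt, probs[1], names = FALSE),
                 upper = stats::quantile(cnt, probs[2], names = FALSE))
    }))
  }))
  }
  iv <- apply(prop_mat, 2, function(col) {
    if (all(is.na(col))) c(NA_real_, NA_real_)
    else stats::quantile(col, probs = probs, na.rm = TRUE, names = FALSE)
  })
  structure(list(mean_proportion = colMeans(prop_mat, na.rm = TRUE),
                 interval = iv, size_counts = size_counts,
                 proportions = prop_mat,
                 n_iter = n_iter, label_counts = unlist(label_counts),
                 interval_mass = interval, seed = seed),
            class = "cluster_null")
}

#' Flag cluster statistics outside the null fluctuation interval
#'
#' An observed clustered proportion (per direction) is significant when it
#' falls outside the central 95\% interval of the permutation null; the
#' side determines whether clustering is enriched or depleted.  Size-class
#' cluster counts are flagged the same way.
#'
#' @param observed a [cluster_summary()] of the real labels.
#' @param null a [cluster_null()] built with matching label counts.
#' @return list of class \code{"cluster_test"}: \code{proportion}
#'   (\code{data.frame} direction/observed/lower/upper/significant/side)
#'   and \code{size_classes}.
#' @export
test_cluster_enrichment <- function(observed, null) {
  if (!isTRUE(all.equal(observed$label_counts[c("male", "female")],
                        null$label_counts[c("male", "female")]))) {
    stop("label counts of observed summary and null do not match")
  }
  dirs <- c("male", "female")
  prop <- do.call(rbind, lapply(seq_along(dirs), function(i) {
    obs <- observed$proportion[[dirs[i]]]
    lo <- null$interval[1, i]; hi <- null$interval[2, i]
    sig <- !is.na(obs) && (obs < lo || obs > hi)
    data.frame(direction = dirs[i], observed = obs, lower = lo, upper = hi,
               significant = sig,
               side = if (!sig) "none" else if (obs > hi) "enriched"
                      else "depleted",
               stringsAsFactors = FALSE)
  }))
  sc <- null$size_counts
  sc$observed <- vapply(seq_len(nrow(sc)), function(i) {
    v <- observed$size_hist$n_clusters[
      observed$size_hist$direction == sc$direction[i] &
      observed$size_hist$size == sc$size[i]]
    if (length(v)) as.numeric(v) else 0
  }, numeric(1))
  sc$significant <- sc$observed < sc$lower | sc$observed > sc$upper
  structure(list(proportion = prop, size_classes = sc),
            class = "cluster_test")
}
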