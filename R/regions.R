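#' Configuration of the sliding-window region scan
#'
#' The scan splits each scaffold into 100-kb bins, slides a 2-Mb window (20
#' bins) in 100-kb steps, computes the mean reassigned log2FC per window,
#' and compares it with an expression-stratified permutation null: genes are
#' grouped into 5 expression strata by baseMean and the reassigned log2FC
#' values are shuffled across gene positions within each stratum.
#'
#' @param bin_size bin width in bp (default 100000).
#' @param window_bins bins per window (default 20, i.e. 2 Mb).
#' @param step_bins step in bins (default 1, i.e. 100 kb).
#' @param n_strata number of expression strata (default 5).
#' @param n_perm number of permutations (default 100000; test-scale runs
#'   use 2000).
#' @param quantile_cutoff quantile defining the per-window significance
#'   cutoff (default 0.9999, i.e. alpha = 1e-4 per tail).
#' @param bonferroni if TRUE, additionally divide alpha by
#'   \code{n_independent}.
#' @param n_independent number of independent (non-overlapping) windows;
#'   NULL = auto: floor(total scaffold length / window span).
#' @param min_genes_per_window windows with fewer member genes are excluded
#'   from calling (default 5).
#' @param seed permutation seed.
#' @return list of class \code{"region_scan_config"}.
#' @export
region_scan_config <- function(bin_size = 1e5, window_bins = 20,
                               step_bins = 1, n_strata = 5,
                               n_perm = 1e5, quantile_cutoff = 0.9999,
                               bonferroni = FALSE, n_independent = NULL,
                               min_genes_per_window = 5, seed = 1L) {
  stopifnot(window_bins >= 1, n_perm >= 100,
            quantile_cutoff > 0.5, quantile_cutoff < 1)
  structure(list(bin_size = bin_size, window_bins = window_bins,
                 step_bins = step_bins, n_strata = n_strata,
                 n_perm = as.integer(n_perm),
                 quantile_cutoff = quantile_cutoff,
                 bonferroni = bonferroni, n_independent = n_independent,
                 min_genes_per_window = min_genes_per_window,
                 seed = as.integer(seed)),
            class = "region_scan_config")
}

#' Assign genes to genomic bins by midpoint
#'
#' Each gene goes to the bin containing its midpoint
#' \code{(start + end) \%/\% 2}; bins are half-open \code{[k*bin, (k+1)*bin)}
#' so a midpoint exactly on a boundary falls in the higher bin.  Each gene
#' is thereby a member of exactly one bin (no double counting at window
#' edges).
#'
#' @param annotation gene annotation (1-based inclusive coordinates).
#' @param cfg a [region_scan_config()].
#' @param scaffold_lengths optional named lengths used to validate
#'   coordinates (default: annotation attribute).
#' @return \code{data.frame}: \code{gene_id}, \code{scaffold}, \code{bin}
#'   (0-based bin index).
#' @export
assign_bins <- function(annotation, cfg = region_scan_config(),
                        scaffold_lengths = NULL) {
  lens <- scaffold_lengths %||% attr(annotation, "scaffold_lengths")
  if (!is.null(lens)) {
    bad <- annotation$end > lens[annotation$scaffold]
    if (any(bad, na.rm = TRUE)) {
      stop("gene(s) beyond scaffold length: ",
           paste(utils::head(annotation$gene_id[which(bad)], 3),
                 collapse = ", "))
    }
  }
  mid <- (annotation$start + annotation$end) %/% 2
  data.frame(gene_id = annotation$gene_id, scaffold = annotation$scaffold,
             bin = mid %/% cfg$bin_size, stringsAsFactors = FALSE)
}

# Window bookkeeping: windows of `window_bins` consecutive bins stepping
# `step_bins`, truncated windows at scaffold ends dropped.  Returns the
# window table plus a sparse window x gene incidence matrix.
build_windows <- function(bin_map, cfg, scaffold_lengths) {
  scafs <- unique(bin_map$scaffold)
  win_list <- list()
  trip_i <- list(); trip_j <- list()
  n_win <- 0L
  for (s in scafs) {
    L <- scaffold_lengths[[s]]
    if (is.null(L) || is.na(L)) L <- max(bin_map$bin[bin_map$scaffold == s] +
                                           1) * cfg$bin_size
    nbins <- ceiling(L / cfg$bin_size)
    starts <- seq(0L, nbins - cfg$window_bins, by = cfg$step_bins)
    if (nbins < cfg$window_bins || !length(starts)) next
    idx <- which(bin_map$scaffold == s)
    b <- bin_map$bin[idx]
    for (k in seq_along(starts)) {
      w <- n_win + k
      members <- idx[b >= starts[k] & b < starts[k] + cfg$window_bins]
      if (length(members)) {
        trip_i[[w]] <- rep.int(w, length(members))
        trip_j[[w]] <- members
      }
    }
    win_list[[s]] <- data.frame(
      scaffold = s,
      start = starts * cfg$bin_size,
      end = pmin((starts + cfg$window_bins) * cfg$bin_size, L),
      stringsAsFactors = FALSE)
    n_win <- n_win + length(starts)
  }
  windows <- do.call(rbind, win_list)
  if (is.null(windows)) {
    warning("no scaffold long enough for a single window")
    windows <- data.frame(scaffold = character(), start = numeric(),
                          end = numeric())
  }
  A <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = 1, dims = c(max(n_win, 1L), nrow(bin_map)))
  list(windows = windows, incidence = A)
}

#' Per-window mean reassigned log2 fold change
#'
#' For every complete sliding window, the mean of the member genes'
#' adjusted log2FC (unexpressed and unbiased genes contribute 0 by the
#' reassignment rule).  Windows with fewer than
#' \code{min_genes_per_window} genes are flagged ineligible and never
#' called.
#'
#' @param values named numeric vector of reassigned log2FC (names = gene
#'   ids, see [reassign_log2fc()]).
#' @param bin_map output of [assign_bins()] covering the same genes.
#' @param cfg a [region_scan_config()].
#' @param scaffold_lengths named scaffold lengths in bp.
#' @return \code{data.frame} of class \code{"window_stats"}:
#'   \code{scaffold}, \code{start}, \code{end} (0-based half-open bp),
#'   \code{n_genes}, \code{mean_log2fc}, \code{eligible}.
#' @export
compute_window_means <- function(values, bin_map, cfg = region_scan_config(),
                                 scaffold_lengths = NULL) {
  bin_map <- bin_map[order(match(bin_map$scaffold, unique(bin_map$scaffold)),
                           bin_map$bin), , drop = FALSE]
  v <- values[bin_map$gene_id]
  stopifnot(!anyNA(v))
  lens <- scaffold_lengths %||% list()
  bw <- build_windows(bin_map, cfg, lens)
  n_genes <- as.vector(bw$incidence %*% rep(1, nrow(bin_map)))
  sums <- as.vector(bw$incidence %*% v)
  out <- bw$windows
  out$n_genes <- n_genes[seq_len(nrow(out))]
  out$mean_log2fc <- ifelse(out$n_genes > 0,
                            sums[seq_len(nrow(out))] / out$n_genes, NaN)
  out$eligible <- out$n_genes >= cfg$min_genes_per_window
  attr(out, "incidence") <- bw$incidence
  attr(out, "gene_order") <- bin_map$gene_id
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Stratify genes by expression level
#'
#' Splits genes into \code{n_strata} quantile categories of baseMean, the
#' guard against expression-level confounding: lowly expressed genes have
#' noisier log2FC, so the permutation null must shuffle values only among
#' genes of comparable expression.  Boundary values go to the lower stratum;
#' unexpressed genes (baseMean 0) fall in stratum 1.
#'
#' @param base_mean named numeric vector (gene ids) of baseMean values.
#' @param n_strata number of strata (default 5).
#' @return named integer vector of stratum labels (1..n_strata).
#' @export
build_strata <- function(base_mean, n_strata = 5) {
  stopifnot(all(base_mean >= 0))
  breaks <- stats::quantile(base_mean,
                            probs = seq_len(n_strata - 1) / n_strata,
                            type = 1, names = FALSE)
  breaks <- unique(breaks)
  if (length(breaks) < n_strata - 1) {
    message("tied baseMean values: fewer than ", n_strata,
            " distinct strata")
  }
  stratum <- vapply(base_mean, function(v) 1L + sum(breaks < v), integer(1))
  stats::setNames(stratum, names(base_mean))
}

#' Expression-stratified permutation null of window means
#'
#' Each iteration shuffles the reassigned log2FC values across gene
#' positions independently within every expression stratum and recomputes
#' all window means.  Per-window exceedance counts against the observed
#' means are accumulated streaming, together with the sorted extreme tails
#' (top and bottom 0.5\%), so memory stays bounded at any \code{n_perm};
#' quantile queries beyond 99.5\% / below 0.5\% are exact.
#'
#' @param values named reassigned log2FC vector.
#' @param strata stratum labels from [build_strata()] (same genes).
#' @param bin_map gene-to-bin map from [assign_bins()].
#' @param cfg a [region_scan_config()]; \code{cfg$n_perm} iterations are
#'   run under \code{cfg$seed}.
#' @param scaffold_lengths named scaffold lengths.
#' @param chunk permutations per block (memory/speed trade-off).
#' @param keep_samples retain the full windows x n_perm matrix of permuted
#'   means (small problems only; memory grows with n_perm).
#' @return list of class \code{"null_distribution"}: \code{n_perm},
#'   \code{count_ge}, \code{count_le} (per window, vs observed),
#'   \code{top}, \code{bottom} (windows x K sorted tail matrices),
#'   \code{observed} (the window table), \code{strata_sizes}, \code{seed}.
#' @export
permute_profiles <- function(values, strata, bin_map,
                             cfg = region_scan_config(),
                             scaffold_lengths = NULL, chunk = 500L,
                             keep_samples = FALSE) {
  if (cfg$n_perm < 100) stop("n_perm < 100: quantiles are meaningless")
  obs <- compute_window_means(values, bin_map, cfg, scaffold_lengths)
  A <- attr(obs, "incidence")
  gene_order <- attr(obs, "gene_order")
  v <- values[gene_order]
  st <- strata[gene_order]
  stopifnot(!anyNA(v), !anyNA(st))
  idx_by_stratum <- split(seq_along(v), st)
  n_win <- nrow(obs)
  n_div <- pmax(obs$n_genes, 1)
  obs_mean <- ifelse(obs$n_genes > 0, obs$mean_log2fc, 0)
  K <- max(ceiling(cfg$n_perm * 0.005), 20L)
  count_ge <- count_le <- numeric(n_win)
  top <- matrix(-Inf, n_win, K)
  bottom <- matrix(Inf, n_win, K)
  samples <- if (keep_samples) matrix(NA_real_, n_win, cfg$n_perm)
  eps <- 1e-12
  with_seed(derive_seed(cfg$seed, 11L), {
    done <- 0L
    while (done < cfg$n_perm) {
      p <- min(chunk, cfg$n_perm - done)
      V <- matrix(0, length(v), p)
      for (ix in idx_by_stratum) {
        if (length(ix) == 1L) {
          V[ix, ] <- v[ix]
        } else {
          for (k in seq_len(p)) V[ix, k] <- v[ix][sample.int(length(ix))]
        }
      }
      M <- as.matrix(A %*% V) / n_div
      count_ge <- count_ge + rowSums(M >= obs_mean - eps)
      count_le <- count_le + rowSums(M <= obs_mean + eps)
      for (w in seq_len(n_win)) {
        top[w, ] <- sort(c(top[w, ], M[w, ]), decreasing = TRUE)[seq_len(K)]
        bottom[w, ] <- sort(c(bottom[w, ], M[w, ]))[seq_len(K)]
      }
      if (keep_samples) samples[, done + seq_len(p)] <- M
      done <- done + p
    }
  })
  structure(list(n_perm = cfg$n_perm, count_ge = count_ge,
                 count_le = count_le, top = top, bottom = bottom,
                 observed = obs, samples = samples,
                 strata_sizes = lengths(idx_by_stratum),
                 seed = cfg$seed),
            class = "null_distribution")
}

#' Exact tail quantile of the permutation null for one window
#'
#' @param null a [permute_profiles()] result.
#' @param window window index.
#' @param prob probability; must lie in the retained tails (>= 0.995 or
#'   <= 0.005).
#' @return the empirical quantile (order statistic, type 1).
#' @export
null_tail_quantile <- function(null, window, prob) {
  n <- null$n_perm
  if (prob >= 0.995) {
    r <- n - ceiling(prob * n) + 1L   # rank from the top
    stopifnot(r <= ncol(null$top))
    null$top[window, r]
  } else if (prob <= 0.005) {
    r <- max(ceiling(prob * n), 1L)
    stopifnot(r <= ncol(null$bottom))
    null$bottom[window, r]
  } else {
    stop("only tail quantiles (<= 0.005 or >= 0.995) are retained")
  }
}

#' Call windows significantly enriched in sex-biased genes
#'
#' Per-window empirical p-values with add-one pseudo-count,
#' \code{p_upper = (1 + #\{perm >= obs\}) / (n_perm + 1)} (male direction;
#' lower tail symmetric for female).  A window is called when its p-value
#' is at most the configured alpha, \code{1 - quantile_cutoff} (1e-4 at the
#' default 99.99\% cutoff), optionally divided by the number of independent
#' windows when \code{bonferroni = TRUE}.  The alpha is floored at
#' \code{1/(n_perm + 1)}, the resolution of the permutation sample: below
#' that, the rule is "more extreme than every permutation".  Windows with
#' too few genes are never called.
#'
#' @param obs observed [compute_window_means()] table (same windows the
#'   null was built on; defaults to \code{null$observed}).
#' @param null a [permute_profiles()] result.
#' @param cfg the [region_scan_config()].
#' @param total_length total scaffold length in bp (for the automatic
#'   n_independent); default inferred from the window table.
#' @return the window table with \code{p_upper}, \code{p_lower},
#'   \code{call} ("male"/"female"/"none") plus attributes
#'   \code{n_independent} and \code{alpha} (the per-window alpha applied).
#' @export
call_enriched_windows <- function(null, cfg = region_scan_config(),
                                  obs = NULL, total_length = NULL) {
  obs <- obs %||% null$observed
  stopifnot(nrow(obs) == length(null$count_ge))
  n <- null$n_perm
  p_upper <- (1 + null$count_ge) / (n + 1)
  p_lower <- (1 + null$count_le) / (n + 1)
  span <- cfg$window_bins * cfg$bin_size
  if (is.null(total_length)) {
    total_length <- sum(tapply(obs$end, obs$scaffold, max))
  }
  n_indep <- cfg$n_independent %||% max(floor(total_length / span), 1)
  alpha <- 1 - cfg$quantile_cutoff
  if (cfg$bonferroni) alpha <- alpha / n_indep
  alpha_eff <- max(alpha, 1 / (n + 1))
  call <- rep("none", nrow(obs))
  call[obs$eligible & p_upper <= alpha_eff] <- "male"
  call[obs$eligible & p_lower <= alpha_eff & call == "none"] <- "female"
  out <- obs
  out$p_upper <- p_upper
  out$p_lower <- p_lower
  out$call <- call
  attr(out, "n_independent") <- n_indep
  attr(out, "alpha") <- alpha_eff
  class(out) <- c("window_calls", "data.frame")
  out
}

#' Merge significant windows into enriched regions
#'
#' Overlapping or adjacent same-direction significant windows on the same
#' scaffold are merged into maximal regions; optionally the member
#' sex-biased genes of the region's direction are listed.
#'
#' @param window_calls a [call_enriched_windows()] table.
#' @param calls optional bias-call table to list member biased genes.
#' @param annotation optional annotation (needed with \code{calls}).
#' @return \code{data.frame}: \code{scaffold}, \code{start}, \code{end},
#'   \code{direction}, \code{n_windows}, \code{gene_ids}
#'   (comma-separated, "" when no \code{calls} given).
#' @export
merge_regions <- function(window_calls, calls = NULL, annotation = NULL) {
  sig <- window_calls[window_calls$call != "none", , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      n_windows = integer(), gene_ids = character(),
                      stringsAsFactors = FALSE))
  }
  sig <- sig[order(sig$scaffold, sig$call, sig$start), , drop = FALSE]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(sig))) {
    row <- sig[i, ]
    if (!is.null(cur) && row$scaffold == cur$scaffold &&
        row$call == cur$direction && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
      cur$n_windows <- cur$n_windows + 1L
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- list(scaffold = row$scaffold, start = row$start, end = row$end,
                  direction = row$call, n_windows = 1L)
    }
  }
  out[[length(out) + 1L]] <- cur
  reg <- do.call(rbind, lapply(out, as.data.frame))
  reg$gene_ids <- ""
  if (!is.null(calls) && !is.null(annotation)) {
    mid <- (annotation$start + annotation$end) %/% 2
    for (i in seq_len(nrow(reg))) {
      members <- annotation$gene_id[annotation$scaffold == reg$scaffold[i] &
                                    mid >= reg$start[i] & mid < reg$end[i]]
      biased <- calls$gene_id[calls$label == reg$direction[i]]
      reg$gene_ids[i] <- paste(intersect(members, biased), collapse = ",")
    }
  }
  reg
}

#' Run the full region scan
#'
#' Convenience wrapper: bin assignment, expression strata, observed window
#' means, stratified permutation null, window calling and region merging.
#'
#' @param annotation gene annotation.
#' @param calls bias-call table for one leg (provides the reassigned
#'   log2FC).
#' @param base_mean named baseMean vector (genes absent get 0).
#' @param cfg a [region_scan_config()].
#' @return list with \code{windows} (called window table), \code{regions},
#'   \code{null}, \code{cfg}.
#' @export
scan_regions <- function(annotation, calls, base_mean,
                         cfg = region_scan_config()) {
  values <- reassign_log2fc(calls)
  values <- values[annotation$gene_id]
  names(values) <- annotation$gene_id
  values[is.na(values)] <- 0
  bm <- base_mean[annotation$gene_id]
  bm[is.na(bm)] <- 0
  names(bm) <- annotation$gene_id
  bin_map <- assign_bins(annotation, cfg)
  strata <- build_strata(bm, cfg$n_strata)
  lens <- attr(annotation, "scaffold_lengths")
  null <- permute_profiles(values, strata, bin_map, cfg, lens)
  win <- call_enriched_windows(null, cfg)
  list(windows = win, regions = merge_regions(win, calls, annotation),
       null = null, cfg = cfg)
}
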