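# Independent brute-force oracles used to check the package's statistics.
# These deliberately re-derive each quantity from first principles and never
# call the code paths they verify.

# Exact two-sided rank-sum p by enumerating all rank splits (no ties).
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  m <- length(x); n <- length(y)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  splits <- utils::combn(m + n, m)
  w_all <- apply(splits, 2, function(ix) sum(rank(pooled)[ix])) -
    m * (m + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (point-probability method).
fisher_p_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive step-up Benjamini-Hochberg.
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Naive FPKM by explicit double loop.
naive_fpkm <- function(counts, lengths) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[, j])
    for (i in seq_len(nrow(counts))) {
      out[i, j] <- counts[i, j] * 1e9 / (lengths[i] * tot)
    }
  }
  out
}

# Naive sliding-window rescan: per scaffold, every complete window of
# `window_bins` bins stepping one bin; genes belong to the bin of their
# midpoint; mean of adjusted values.
naive_window_means <- function(values, annotation, bin_size, window_bins,
                               scaffold_lengths) {
  out <- list()
  for (s in unique(annotation$scaffold)) {
    sub <- annotation[annotation$scaffold == s, ]
    L <- scaffold_lengths[[s]]
    nbins <- ceiling(L / bin_size)
    mids <- (sub$start + sub$end) %/% 2
    bins <- mids %/% bin_size
    for (k in 0:(nbins - window_bins)) {
      members <- sub$gene_id[bins >= k & bins < k + window_bins]
      out[[length(out) + 1L]] <- data.frame(
        scaffold = s, start = k * bin_size,
        n_genes = length(members),
        mean_log2fc = if (length(members)) mean(values[members]) else NaN)
    }
  }
  do.call(rbind, out)
}

# Small default simulation reused across tests (kept small for speed).
small_sim_config <- function(seed = 42, ...) {
  simulation_config(n_autosomes = 3,
                    scaffold_lengths = rep(2e6, 4),
                    x_scaffold_index = 4, seed = seed, ...)
}
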