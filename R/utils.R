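#' @importFrom stats rnbinom rlnorm rexp rgamma rpois runif median quantile
#' @importFrom stats prcomp p.adjust wilcox.test fisher.test setNames rnorm
#' @importFrom utils write.table read.table head
NULL

# Deterministic child seeds so each generator stage can be reproduced on its
# own.  Kept strictly below 2^31 - 1.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483629)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Commercial rounding (0.005 -> 0.01), used for reported percentages so that
#' printed summary tables are reproduced digit for digit.  Base R's
#' \code{round()} rounds half to even and would turn e.g. 16.035 into 16.03
#' or 16.04 depending on binary representation.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a total, rounded to two decimals
#'
#' @param count numerator count.
#' @param total denominator count.
#' @param digits decimal places (default 2).
#' @return percentage on the 0--100 scale, rounded half away from zero.
#' @export
percentage <- function(count, total, digits = 2) {
  ifelse(total > 0, round_half_away(100 * count / total, digits), NA_real_)
}

# Two-sided rank-sum test.  Exact when sample sizes are small and there are
# no ties (wilcox.test's own rule); otherwise the normal approximation
# without continuity correction, so that identical multisets give p = 1.
ranksum_test <- function(x, y) {
  res <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                             correct = FALSE))
  p <- res$p.value
  # fully tied samples: the normal approximation degenerates (0/0)
  if (is.nan(p)) p <- 1
  list(statistic = unname(res$statistic), p.value = min(p, 1))
}

# Benjamini-Hochberg, delegated to stats::p.adjust (oracle-checked in tests).
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

`%||%` <- function(a, b) if (is.null(a)) b else a
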