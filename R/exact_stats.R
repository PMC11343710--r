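# Exact two-sided Wilcoxon rank-sum (Mann-Whitney) p-values via the standard
# partition-count dynamic programme.  No ties, no normal approximation.

#' Exact null distribution of the Mann-Whitney statistic
#'
#' Number of ways to choose `n1` of the ranks `1..(n1+n2)` so that the
#' Mann-Whitney statistic (rank sum of group 1 minus its minimum
#' `n1(n1+1)/2`) equals each value `W = 0..n1*n2`, by the recurrence
#' `c(m, n, W) = c(m-1, n, W-n) + c(m, n-1, W)`.
#'
#' @param n1,n2 group sizes, both at least 1.
#' @param max_cells guard on the DP table size `n1*n2` (refuse beyond it and
#'   point at a normal approximation, which this package deliberately does
#'   not provide).
#' @return numeric vector `counts` of length `n1*n2 + 1`, where
#'   `counts[W + 1]` is the subset count for statistic `W`; the counts sum to
#'   `choose(n1 + n2, n1)`.
#' @export
ranksum_counts <- function(n1, n2, max_cells = 1e6) {
  dk_assert(n1 >= 1 && n2 >= 1, "group sizes must be at least 1")
  dk_assert(n1 * n2 <= max_cells,
            sprintf("DP table of %g cells exceeds the cap (%g); use a normal approximation outside this package",
                    n1 * n2, max_cells), "dk_size_error")
  # N(W; m, n) = N(W; m, n-1) + N(W - n; m - 1, n): condition on whether the
  # largest of the m + n ranks sits in group 2 (drops it, W unchanged) or in
  # group 1 (it beats all n group-2 values, contributing n to W).
  maxW <- n1 * n2
  N <- matrix(0, nrow = n1 + 1, ncol = maxW + 1)
  N[, 1] <- 1  # n = 0: only W = 0, for every m
  for (n in seq_len(n2)) {
    Nn <- matrix(0, nrow = n1 + 1, ncol = maxW + 1)
    Nn[1, 1] <- 1  # m = 0
    for (m in seq_len(n1)) {
      Nn[m + 1, ] <- N[m + 1, ]
      idx <- seq_len(maxW + 1 - n)
      Nn[m + 1, idx + n] <- Nn[m + 1, idx + n] + Nn[m, idx]
    }
    N <- Nn
  }
  out <- N[n1 + 1, ]
  names(out) <- 0:maxW
  out
}

#' Exact two-sided Wilcoxon rank-sum p-value
#'
#' Two-sided p-value for an observed Mann-Whitney statistic under the exact
#' permutation null, doubling the smaller (inclusive) tail and capping at 1 —
#' the convention of standard statistical software. Tied data (non-integer
#' `W`) are rejected rather than approximated.
#'
#' @param n1,n2 group sizes.
#' @param W observed Mann-Whitney statistic in `[0, n1*n2]`; integer.
#' @return an object of class `ranksum_result`: list with `n1`, `n2`, `W`,
#'   `p_two_sided`.
#' @export
wilcoxon_exact_p <- function(n1, n2, W) {
  dk_assert(length(W) == 1 && is.finite(W), "W must be a single finite value")
  if (abs(W - round(W)) > 1e-9) {
    dk_error("non-integer W implies tied data; the exact test is undefined for ties",
             "dk_ties_error")
  }
  W <- as.integer(round(W))
  dk_assert(W >= 0 && W <= n1 * n2, "W must lie in [0, n1*n2]")
  counts <- ranksum_counts(n1, n2)
  total <- sum(counts)
  lo <- sum(counts[seq_len(W + 1)]) / total          # P(W' <= W)
  hi <- sum(counts[(W + 1):length(counts)]) / total  # P(W' >= W)
  p <- min(1, 2 * min(lo, hi))
  structure(list(n1 = n1, n2 = n2, W = W, p_two_sided = p),
            class = "ranksum_result")
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf("Exact Wilcoxon rank-sum: n1 = %d, n2 = %d, W = %d, two-sided P = %.4g\n",
              x$n1, x$n2, x$W, x$p_two_sided))
  invisible(x)
}

#' Exact rank-sum test from raw values
#'
#' Computes the Mann-Whitney statistic for two samples (counting, for each
#' member of group 1, how many of group 2 it exceeds) and calls
#' [wilcoxon_exact_p()]. Tied observations across groups are rejected.
#'
#' @param x,y numeric vectors (group 1 and group 2).
#' @return a `ranksum_result`.
#' @export
ranksum_test <- function(x, y) {
  dk_assert(length(intersect(x, y)) == 0 && !anyDuplicated(c(x, y)),
            "tied observations are not supported by the exact test")
  W <- sum(outer(x, y, ">"))
  wilcoxon_exact_p(length(x), length(y), W)
}
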