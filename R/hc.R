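# Higher Criticism: a goodness-of-fit style statistic on the empirical
# distribution of p-values, powerful against rare-weak alternatives where a
# small fraction of tests carry effects too weak for individual detection.

hc_variants <- c("hc_plus", "hc2004")

# Core evaluation on an already-sorted, already-clipped p-vector.
hc_core <- function(ps, variant, alpha0) {
  n <- length(ps)
  i_max <- max(1L, floor(alpha0 * n))
  i <- seq_len(i_max)
  ps <- ps[i]
  hc_i <- sqrt(n) * (i / n - ps) / sqrt(ps * (1 - ps))
  if (variant == "hc_plus") {
    keep <- ps > 1 / n
    # all order statistics below 1/n: overwhelming signal; fall back to the
    # unrestricted maximum so the statistic stays defined (and equals hc2004)
    if (any(keep)) hc_i <- hc_i[keep]
  }
  max(hc_i)
}

#' Higher Criticism statistic
#'
#' Sorts the p-values ascending and standardizes the gap between each order
#' statistic and its uniform-null expectation:
#' `HC = max_i sqrt(N) (i/N - p_(i)) / sqrt(p_(i) (1 - p_(i)))`, the maximum
#' taken over `i <= floor(alpha0 N)`. The `"hc_plus"` variant (default)
#' additionally restricts to order statistics with `p_(i) > 1/N`, which
#' stabilizes the statistic against a few extreme p-values; consequently
#' `hc_plus <= hc2004` on any input. The statistic can be negative (p-values
#' larger than their null expectation).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`, length >= 2.
#' @param variant `"hc_plus"` or `"hc2004"`.
#' @param alpha0 Fraction of the smallest order statistics searched
#'   (default 0.5).
#' @return The HC statistic (scalar).
#' @export
hc_statistic <- function(pvalues, variant = c("hc_plus", "hc2004"),
                         alpha0 = 0.5) {
  variant <- match.arg(variant)
  if (!length(pvalues) || length(pvalues) < 2)
    stop("need at least 2 p-values")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stopifnot(alpha0 > 0, alpha0 <= 1)
  # guard exact 0/1 only; clipping anywhere near 1/N would distort the
  # maximum at small N
  ps <- pmin(pmax(sort(pvalues), 1e-10), 1 - 1e-10)
  hc_core(ps, variant, alpha0)
}

#' Monte-Carlo null distribution of the HC statistic
#'
#' Computes the HC statistic on independent uniform(0,1) p-value samples of
#' the observed size. The resulting sample calibrates the test: the HC null
#' distribution depends on N (and the variant), and its finite-sample
#' quantiles are far from the asymptotic sqrt(2 log log N) regime at the
#' sizes connectome analyses use.
#'
#' @param n_pvalues Number of p-values in each null replicate.
#' @param variant,alpha0 As in [hc_statistic()].
#' @param n_replicates Number of null replicates (>= 1000).
#' @param seed Integer seed.
#' @return Object of class `hc_null`: sorted null sample plus cached
#'   quantiles and parameters.
#' @export
hc_null_distribution <- function(n_pvalues, variant = c("hc_plus", "hc2004"),
                                 alpha0 = 0.5, n_replicates = 10000,
                                 seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(n_replicates >= 1000, n_pvalues >= 2)
  values <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(r) {
      ps <- pmin(pmax(sort(stats::runif(n_pvalues)), 1e-10), 1 - 1e-10)
      hc_core(ps, variant, alpha0)
    }, numeric(1))
  })
  values <- sort(values)
  structure(list(values = values, n_pvalues = as.integer(n_pvalues),
                 variant = variant, alpha0 = alpha0,
                 n_replicates = as.integer(n_replicates), seed = seed,
                 quantiles = stats::quantile(values, c(0.9, 0.95, 0.99),
                                             names = TRUE)),
            class = "hc_null")
}

#' Higher Criticism joint-hypothesis test
#'
#' Compares the observed HC statistic with its Monte-Carlo null sample. The
#' empirical p-value uses the add-one continuity correction
#' `(1 + #(null >= observed)) / (M + 1)`; the joint null of no effects
#' anywhere is rejected when it is at most `alpha`. A p-value histogram is
#' attached as the plausibility diagnostic.
#'
#' @param pvalues Observed p-values.
#' @param null An [hc_null_distribution()] whose size and variant match.
#' @param alpha Test level (default 0.05).
#' @param n_bins Histogram bins for the diagnostic (default 20).
#' @return Object of class `hc_result` with fields `n_pvalues`, `variant`,
#'   `alpha0`, `hc_value`, `null_quantile_95`, `empirical_p`, `reject`,
#'   `histogram`.
#' @export
hc_test <- function(pvalues, null, alpha = 0.05, n_bins = 20) {
  stopifnot(inherits(null, "hc_null"))
  if (length(pvalues) != null$n_pvalues)
    stop("null sample was calibrated for ", null$n_pvalues,
         " p-values, got ", length(pvalues))
  hc <- hc_statistic(pvalues, variant = null$variant, alpha0 = null$alpha0)
  m <- null$n_replicates
  emp_p <- (1 + sum(null$values >= hc)) / (m + 1)
  structure(list(n_pvalues = length(pvalues), variant = null$variant,
                 alpha0 = null$alpha0, hc_value = hc,
                 null_quantile_95 = unname(null$quantiles["95%"]),
                 empirical_p = emp_p, alpha = alpha,
                 reject = emp_p <= alpha,
                 histogram = pvalue_histogram(pvalues, n_bins)),
            class = "hc_result")
}

#' @export
print.hc_result <- function(x, ...) {
  cat(sprintf("Higher Criticism test (%s, alpha0 = %g) on %d p-values\n",
              x$variant, x$alpha0, x$n_pvalues))
  cat(sprintf("  HC = %.4f (null 95%% quantile %.4f)\n",
              x$hc_value, x$null_quantile_95))
  cat(sprintf("  empirical p = %.4g -> %s at alpha = %g\n", x$empirical_p,
              if (x$reject) "reject joint null" else "retain joint null",
              x$alpha))
  cat(sprintf("  first-bin excess ratio: %.2f\n",
              x$histogram$first_bin_excess))
  invisible(x)
}

#' P-value histogram diagnostic
#'
#' Equal-width bins on `[0, 1]`. Under the joint null the counts are flat;
#' an excess in the first bin is the visual signature of non-zero effects.
#' The observed/expected ratio of the first bin is reported as a
#' plausibility diagnostic for the HC result.
#'
#' @param pvalues P-values in `[0, 1]`.
#' @param n_bins Number of bins (default 20).
#' @return List with `counts` (summing to `length(pvalues)`), `breaks` and
#'   `first_bin_excess`.
#' @export
pvalue_histogram <- function(pvalues, n_bins = 20) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(ceiling(pvalues * n_bins), 1L), n_bins),
                     nbins = n_bins)
  list(counts = counts, breaks = breaks,
       first_bin_excess = counts[1] / (length(pvalues) / n_bins))
}
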