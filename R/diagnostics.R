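#' Pairwise correlation diagnostics for a feature matrix
#'
#' Quantifies multicollinearity among extracted features: Pearson
#' correlation for every feature pair (over the first `max_features`
#' columns), two-sided p-values from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, a
#' 10-bin p-value histogram, and the fraction of pairs with `p < 0.1`.
#' Heavily collinear feature sets pile the p-value mass into the first bin.
#' Constant columns have undefined correlations; they are dropped from the
#' pair set and counted.
#'
#' @param x Feature matrix with at least 3 rows.
#' @param max_features Cap on the number of (leading) columns entering the
#'   pair enumeration (default 200; the full 4096-wide matrices would give
#'   8M pairs for no diagnostic gain).
#' @return A `correlation_report`: `$r` and `$p` (symmetric matrices over
#'   the evaluated columns), `$pairs` (data frame i, j, r, p over the upper
#'   triangle), `$histogram` (10 counts), `$frac_p_below_0.1`,
#'   `$n_constant_excluded`, `$n_samples`.
#' @export
pairwise_correlation <- function(x, max_features = 200L) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stopf("correlation diagnostics require at least 3 samples")
  x <- x[, seq_len(min(ncol(x), max_features)), drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  n_const <- sum(const)
  if (n_const > 0L) {
    message(sprintf("pairwise_correlation: excluding %d constant column(s)", n_const))
    x <- x[, !const, drop = FALSE]
  }
  n <- nrow(x); m <- ncol(x)
  r <- stats::cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  ut <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- data.frame(i = ut[, 1L], j = ut[, 2L],
                      r = r[upper.tri(r)], p = p[upper.tri(p)])
  hist <- pvalue_histogram(pairs$p)
  structure(list(r = r, p = p, pairs = pairs, histogram = hist,
                 frac_p_below_0.1 = if (nrow(pairs)) mean(pairs$p < 0.1) else NA_real_,
                 n_constant_excluded = n_const, n_samples = n),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Correlation report: %d features, %d pairs, n = %d\n",
              ncol(x$r), nrow(x$pairs), x$n_samples))
  cat(sprintf("  fraction of pairs with p < 0.1: %.3f\n", x$frac_p_below_0.1))
  cat("  p-value histogram (10 bins over [0,1]):", x$histogram, "\n")
  if (x$n_constant_excluded)
    cat(sprintf("  constant columns excluded: %d\n", x$n_constant_excluded))
  invisible(x)
}

#' Histogram of p-values over equal-width bins
#'
#' Bins are `[0, 1/bins), [1/bins, 2/bins), ..., [1 - 1/bins, 1]` (the last
#' bin is right-closed so `p = 1` is counted).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param bins Number of bins (default 10).
#' @return Integer vector of counts, one per bin; counts sum to `length(p)`.
#' @export
pvalue_histogram <- function(p, bins = 10L) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0,1]")
  bins <- as.integer(bins)
  idx <- pmin(floor(p * bins) + 1L, bins)
  tabulate(idx, nbins = bins)
}
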