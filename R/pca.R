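#' Covariance PCA with eigenvalue-magnitude ranking
#'
#' Fits principal components by eigendecomposition of the sample covariance
#' matrix (divisor `n - 1`), with components sorted by decreasing eigenvalue
#' magnitude. Ties in `|lambda|` keep the original eigen-index order, and
#' each eigenvector's sign is fixed so its largest-magnitude entry is
#' positive, making the basis fully reproducible. No variance scaling is
#' applied: the decomposition is of the covariance, not the correlation,
#' matrix. When there are more features than samples the same eigenproblem
#' is solved through the n x n Gram matrix (identical nonzero eigenvalues
#' and directions).
#'
#' @param x Numeric matrix, samples in rows (`n >= 2`), features in columns.
#' @param class_tag Internal: tag recorded on the fitted components.
#' @return A `pca_basis` object: unit-norm component directions (columns of
#'   `$rotation`), eigenvalues, the fitting mean per component group, the
#'   full eigenvalue spectrum per group (for retained-energy curves), `$mode`
#'   (`"pooled"` here) and `$K` (all stored components).
#' @seealso [fit_classwise_pca()], [project_pca()], [retained_energy()]
#' @export
fit_pca <- function(x, class_tag = "pooled") {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopf("PCA requires at least 2 samples")
  if (ncol(x) < 1L) stopf("PCA requires at least 1 feature")
  mu <- colMeans(x)
  n <- nrow(x); p <- ncol(x)
  if (p <= n) {
    eig <- eigen(stats::cov(x), symmetric = TRUE)
    values <- eig$values
    vectors <- eig$vectors
  } else {
    xc <- sweep(x, 2L, mu, "-")
    eig <- eigen(tcrossprod(xc) / (n - 1), symmetric = TRUE)
    keep <- seq_len(max(1L, sum(eig$values > max(eig$values[1], 0) * 1e-12)))
    values <- eig$values[keep]
    # feature-space directions recovered from the sample-space eigenvectors
    vectors <- crossprod(xc, eig$vectors[, keep, drop = FALSE])
    vectors <- sweep(vectors, 2L, sqrt(pmax(values, .Machine$double.eps) * (n - 1)), "/")
  }
  ord <- order(-abs(values), seq_along(values))
  values <- values[ord]
  vectors <- vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vectors))) {
    v <- vectors[, j]
    if (v[which.max(abs(v))] < 0) vectors[, j] <- -v
  }
  basis <- list(mode = "pooled", K = length(values), dim = p,
                rotation = vectors, eigenvalues = values,
                class_tag = rep(class_tag, length(values)),
                group_means = stats::setNames(list(mu), class_tag),
                group_eigenvalues = stats::setNames(list(values), class_tag))
  class(basis) <- "pca_basis"
  basis
}

#' Class-wise PCA combined across classes
#'
#' Fits a separate covariance PCA on each class's training rows (each with
#' its own class mean), keeps the top `k_per_class` components of each by
#' eigenvalue magnitude, and concatenates the class blocks in label-sorted
#' order. Each component carries the mean of its own fitting class, so the
#' combined projection is a fixed affine map. This yields class-specific
#' directions that a pooled fit averages away.
#'
#' @param x Numeric matrix, samples in rows.
#' @param y Class labels (any number of classes, each with `>= 2` samples).
#' @param k_per_class Components retained per class.
#' @return A `pca_basis` with `mode = "per_class"` and
#'   `K = k_per_class * nlevels(y)`.
#' @export
fit_classwise_pca <- function(x, y, k_per_class) {
  x <- as.matrix(x)
  y <- factor(y)
  k_per_class <- as.integer(k_per_class)
  if (k_per_class < 1L) stopf("k_per_class must be at least 1")
  classes <- sort(levels(y))
  rot <- NULL; vals <- NULL; tags <- character(0)
  gm <- list(); ge <- list()
  for (cl in classes) {
    rows <- which(y == cl)
    if (length(rows) < 2L) stopf("class '%s' has fewer than 2 samples", cl)
    b <- fit_pca(x[rows, , drop = FALSE], class_tag = cl)
    if (k_per_class > b$K)
      stopf("class '%s' supports at most %d components, requested %d", cl, b$K, k_per_class)
    keep <- seq_len(k_per_class)
    rot <- cbind(rot, b$rotation[, keep, drop = FALSE])
    vals <- c(vals, b$eigenvalues[keep])
    tags <- c(tags, rep(cl, k_per_class))
    gm[[cl]] <- b$group_means[[cl]]
    ge[[cl]] <- b$group_eigenvalues[[cl]]
  }
  basis <- list(mode = "per_class", K = length(vals), dim = ncol(x),
                rotation = rot, eigenvalues = vals, class_tag = tags,
                group_means = gm, group_eigenvalues = ge)
  class(basis) <- "pca_basis"
  basis
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("<pca_basis mode=%s K=%d dim=%d groups=%s>\n", x$mode, x$K, x$dim,
              paste(names(x$group_means), collapse = ",")))
  invisible(x)
}

#' Project samples onto a fitted PCA basis
#'
#' Score for component `j` of sample `x` is `v_j' (x - mu_j)` where `mu_j`
#' is the mean recorded at fitting time for that component's group (the
#' pooled mean, or the component's class mean in per-class mode).
#'
#' @param x Numeric matrix with the same feature count as the basis.
#' @param basis A `pca_basis`.
#' @param K Number of leading components to score (default: all stored).
#' @return An n x K score matrix; attribute `column_meta` is a data frame
#'   with each column's `class_tag` and within-group `rank`.
#' @export
project_pca <- function(x, basis, K = basis$K) {
  x <- as.matrix(x)
  if (ncol(x) != basis$dim)
    stopf("feature count %d does not match basis dimensionality %d", ncol(x), basis$dim)
  K <- as.integer(K)
  if (K < 1L || K > basis$K) stopf("K must be between 1 and %d", basis$K)
  scores <- matrix(0, nrow(x), K)
  rank_in_group <- stats::ave(seq_len(basis$K), basis$class_tag, FUN = seq_along)
  for (tag in unique(basis$class_tag[seq_len(K)])) {
    cols <- which(basis$class_tag[seq_len(K)] == tag)
    xc <- sweep(x, 2L, basis$group_means[[tag]], "-")
    scores[, cols] <- xc %*% basis$rotation[, cols, drop = FALSE]
  }
  colnames(scores) <- sprintf("PC%d", seq_len(K))
  rownames(scores) <- rownames(x)
  attr(scores, "column_meta") <- data.frame(class_tag = basis$class_tag[seq_len(K)],
                                            rank = rank_in_group[seq_len(K)],
                                            stringsAsFactors = FALSE)
  scores
}

#' Retained energy of the leading principal components
#'
#' Fraction of total eigenvalue magnitude captured by the top `k` components
#' of each fitting group: `sum(|lambda_1..k|) / sum(|lambda|)` over the full
#' spectrum recorded at fitting time. Pooled bases give a single fraction;
#' per-class bases one fraction per class.
#'
#' @param basis A `pca_basis`.
#' @param k Number of leading components, `1 <= k <=` stored spectrum size.
#' @return Named numeric vector of fractions in `[0, 1]` (length 1 for
#'   pooled mode).
#' @export
retained_energy <- function(basis, k) {
  k <- as.integer(k)
  out <- vapply(basis$group_eigenvalues, function(ev) {
    if (k < 1L || k > length(ev)) stopf("k must be between 1 and %d", length(ev))
    a <- abs(ev)
    sum(a[seq_len(k)]) / sum(a)
  }, numeric(1))
  if (basis$mode == "pooled") unname(out[1]) else out
}
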