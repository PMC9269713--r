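#' LR-PCA: logistic-regression-guided principal component selection
#'
#' The package's core feature-reduction model. Deep-feature matrices are
#' strongly multicollinear; `lrpca` removes the collinearity and keeps only
#' the class-relevant directions in three steps, all fitted on training rows
#' only:
#'
#' 1. Covariance PCA ranked by eigenvalue magnitude, either pooled over all
#'    samples (`mode = "pooled"`) or fitted on each class separately and
#'    combined (`mode = "per_class"`, `ceiling(K / n_classes)` components per
#'    class), keeping the top `K` components.
#' 2. A binomial logistic regression of the class labels on the `K` PC
#'    scores, with Wald standard errors, t statistics and p-values per
#'    coefficient.
#' 3. Selection of the components whose coefficients are significant at
#'    level `alpha` (`p < alpha`).
#'
#' The returned object is a fixed affine transform: apply it to new data
#' with [predict()] to obtain the selected score columns (no refitting, no
#' leakage).
#'
#' @param x Numeric feature matrix, samples in rows.
#' @param y Binary class labels (two-level factor, character or 0/1).
#' @param mode `"pooled"` (PCA across all training samples) or `"per_class"`
#'   (class-wise PCA blocks combined).
#' @param K Total number of principal components fed to the logistic model
#'   (default 50). Capped at the number of available components with a
#'   message.
#' @param alpha Wald significance level for selection (default 0.05).
#' @param ... Passed to [fit_binomial_lr()] (tolerances, ridge).
#' @return An object of class `lrpca` with elements `basis` (the
#'   [fit_pca()]/[fit_classwise_pca()] result), `lr` (the [fit_binomial_lr()]
#'   fit), `selection` ([select_significant()]), `scores` (training scores,
#'   all `K` columns), `K`, `alpha`, `mode`, `levels`.
#' @examples
#' sim <- simulate_features(n = 120, p = 16, r = 4, n_informative = 2, seed = 1)
#' fit <- lrpca(sim$x, sim$y, mode = "pooled", K = 10)
#' summary(fit)
#' head(predict(fit, sim$x))
#' @export
lrpca <- function(x, y, mode = c("pooled", "per_class"), K = 50L, alpha = 0.05, ...) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2L) stopf("lrpca requires exactly 2 classes, found %d", nlevels(y))
  K <- as.integer(K)
  if (K < 1L) stopf("K must be at least 1")
  if (mode == "pooled") {
    basis <- fit_pca(x)
    if (K > basis$K) {
      message(sprintf("K reduced from %d to %d available components", K, basis$K))
      K <- basis$K
    }
  } else {
    k_per_class <- as.integer(ceiling(K / nlevels(y)))
    max_k <- min(table(y)) - 1L
    if (k_per_class > max_k) {
      message(sprintf("k_per_class reduced from %d to %d available components",
                      k_per_class, max_k))
      k_per_class <- max_k
    }
    basis <- fit_classwise_pca(x, y, k_per_class)
    K <- basis$K
  }
  scores <- project_pca(x, basis, K = K)
  lr <- fit_binomial_lr(scores, y, ...)
  sel <- select_significant(lr, alpha = alpha)
  structure(list(basis = basis, lr = lr, selection = sel, scores = scores,
                 K = K, alpha = alpha, mode = mode, levels = levels(y),
                 call = match.call()),
            class = "lrpca")
}

#' Predict method: project new samples and keep the selected components
#'
#' @param object An `lrpca` fit.
#' @param newdata Feature matrix with the same columns as the training data.
#' @param type `"selected"` (default): score columns chosen by the Wald
#'   selection; `"scores"`: all `K` score columns; `"response"`: fitted
#'   probability of the positive (second) class from the internal logistic
#'   model; `"class"`: thresholded labels.
#' @param ... Unused.
#' @return Matrix of scores, or a numeric/factor vector for
#'   `"response"`/`"class"`.
#' @export
predict.lrpca <- function(object, newdata,
                          type = c("selected", "scores", "response", "class"), ...) {
  type <- match.arg(type)
  scores <- project_pca(as.matrix(newdata), object$basis, K = object$K)
  if (type == "scores") return(scores)
  if (type == "selected") return(scores[, object$selection$selected, drop = FALSE])
  beta <- object$lr$coefficients$estimate
  eta <- drop(cbind(1, scores) %*% beta)
  if (type == "response") return(stats::plogis(eta))
  factor(object$levels[(eta > 0) + 1L], levels = object$levels)
}

#' @export
coef.lrpca <- function(object, ...) {
  stats::setNames(object$lr$coefficients$estimate, object$lr$coefficients$term)
}

#' @export
print.lrpca <- function(x, ...) {
  cat("LR-PCA feature reduction\n")
  cat(sprintf("  mode: %s   K: %d   alpha: %g\n", x$mode, x$K, x$alpha))
  cat(sprintf("  selected components: %d of %d\n", length(x$selection$selected), x$K))
  if (length(x$selection$selected))
    cat("  ", paste(colnames(x$scores)[x$selection$selected], collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.lrpca <- function(object, ...) {
  tab <- object$lr$coefficients
  tab$selected <- c(FALSE, seq_len(object$K) %in% object$selection$selected)
  meta <- attr(object$scores, "column_meta")
  tab$class_tag <- c(NA, meta$class_tag)
  structure(list(table = tab, mode = object$mode, K = object$K,
                 alpha = object$alpha, converged = object$lr$converged,
                 n_selected = length(object$selection$selected),
                 energy = retained_energy_curve(object$basis)),
            class = "summary.lrpca")
}

#' @export
print.summary.lrpca <- function(x, ...) {
  cat(sprintf("LR-PCA (%s mode, K = %d, alpha = %g): %d components selected\n",
              x$mode, x$K, x$alpha, x$n_selected))
  cat(sprintf("  logistic fit converged: %s\n\n", x$converged))
  tab <- x$table
  tab$p <- format.pval(tab$p, digits = 3)
  print(tab, digits = 4, row.names = FALSE)
  invisible(x)
}

retained_energy_curve <- function(basis) {
  kmax <- min(lengths(basis$group_eigenvalues))
  vapply(seq_len(kmax), function(k) mean(retained_energy(basis, k)), numeric(1))
}

#' Plot method: retained-energy curve of the fitted basis
#'
#' Cumulative fraction of eigenvalue magnitude captured by the leading
#' components, one curve per fitting group (classes in per-class mode), with
#' the model's `K` marked.
#'
#' @param x An `lrpca` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lrpca <- function(x, ...) {
  ge <- x$basis$group_eigenvalues
  kmax <- max(lengths(ge))
  graphics::plot(NULL, xlim = c(1, kmax), ylim = c(0, 1),
                 xlab = "components k", ylab = "retained energy", ...)
  for (i in seq_along(ge)) {
    a <- abs(ge[[i]])
    graphics::lines(seq_along(a), cumsum(a) / sum(a), lty = i)
  }
  graphics::abline(v = min(x$K, kmax), col = "grey50", lty = 3)
  graphics::legend("bottomright", legend = names(ge), lty = seq_along(ge), bty = "n")
  invisible(x)
}

#' One-call LR-PCA reduction of a train/other pair
#'
#' Convenience wrapper around [lrpca()]: fits the basis, logistic model and
#' selection on the training rows only, then applies the resulting fixed
#' transform to a second matrix (validation or test rows), guaranteeing no
#' leakage.
#'
#' @param x_train,y_train Training features and binary labels.
#' @param x_other Feature matrix transformed with the training fit (may be
#'   `NULL`).
#' @param mode,K,alpha See [lrpca()].
#' @param ... Passed to [lrpca()].
#' @return List with `train` and `other` (selected score matrices), `fit`
#'   (the `lrpca` object), `basis`, `lr` and `selection`.
#' @export
lr_pca_reduce <- function(x_train, y_train, x_other = NULL,
                          mode = c("pooled", "per_class"), K = 50L, alpha = 0.05, ...) {
  fit <- lrpca(x_train, y_train, mode = match.arg(mode), K = K, alpha = alpha, ...)
  list(train = fit$scores[, fit$selection$selected, drop = FALSE],
       other = if (!is.null(x_other)) predict(fit, x_other, type = "selected"),
       fit = fit, basis = fit$basis, lr = fit$lr, selection = fit$selection)
}
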