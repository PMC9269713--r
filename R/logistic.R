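#' Binomial logistic regression with Wald coefficient statistics
#'
#' Maximum-likelihood fit with intercept via iteratively reweighted least
#' squares (deviance tolerance `1e-8`, at most 100 iterations). Standard
#' errors come from the inverse of the observed information at the optimum,
#' `t = beta / SE`, and two-sided p-values from the standard-normal reference
#' for the Wald statistic.
#'
#' If the fit does not converge or quasi-separation is detected (fitted
#' probabilities collapsing to 0/1 with diverging coefficients), the model
#' is refit and flagged accordingly so degenerate folds never abort a
#' pipeline run. The default fallback is Firth's bias-reduced logistic
#' regression (Jeffreys-prior penalized likelihood), the standard remedy
#' for separation: it always yields finite coefficients and usable Wald
#' statistics, which matters here because near-separable score matrices
#' are exactly the regime a well-performing CAD pipeline produces. A plain
#' ridge fallback (`1e-6`) is also available; note that under true
#' separation it leaves the Wald statistics degenerate (enormous standard
#' errors), so significance-based selection will come back empty.
#'
#' @param scores Numeric matrix of predictors (e.g. PC scores), one column
#'   per coefficient; `nrow(scores)` must exceed `ncol(scores) + 1`.
#' @param y Binary outcome: logical, 0/1, or a two-level factor (the second
#'   sorted level is the positive class).
#' @param tol Convergence tolerance (deviance change for the MLE path,
#'   coefficient step for the Firth path).
#' @param max_iter Maximum IRLS iterations.
#' @param separation Fallback on non-convergence/separation: `"firth"`
#'   (default) or `"ridge"`.
#' @param ridge Ridge penalty used when `separation = "ridge"`.
#' @return A `binomial_lr` object with `$coefficients` (data frame: term,
#'   estimate, se, t, p; intercept first), `$converged`, `$iterations`,
#'   `$method` (`"mle"`, `"firth"` or `"ridge"`), `$fitted` and `$levels`.
#' @export
fit_binomial_lr <- function(scores, y, tol = 1e-8, max_iter = 100L,
                            separation = c("firth", "ridge"), ridge = 1e-6) {
  separation <- match.arg(separation)
  scores <- as.matrix(scores)
  yb <- binary_response(y)
  n <- nrow(scores); K <- ncol(scores)
  if (length(yb$y01) != n) stopf("length of y must match rows of scores")
  if (length(unique(yb$y01)) < 2L) stopf("y must contain both classes")
  if (n <= K + 1L) stopf("need more samples (%d) than coefficients (%d)", n, K + 1L)
  X <- cbind(`(Intercept)` = 1, scores)
  if (is.null(colnames(scores))) colnames(X)[-1L] <- sprintf("x%d", seq_len(K))

  res <- irls_logistic(X, yb$y01, lambda = 0, tol = tol, max_iter = max_iter)
  # saturated fitted probabilities signal (quasi-)separation: a clean MLE
  # keeps |eta| moderate, so p_hat at the double-precision boundary means
  # diverging coefficients and degenerate Wald statistics
  separated <- any(res$p_hat < 1e-8 | res$p_hat > 1 - 1e-8)
  method <- "mle"
  if (!res$converged || separated || !res$ok) {
    res <- if (separation == "firth") {
      firth_logistic(X, yb$y01, tol = tol, max_iter = max(max_iter, 200L))
    } else {
      irls_logistic(X, yb$y01, lambda = ridge, tol = tol, max_iter = max_iter)
    }
    method <- separation
  }

  se <- sqrt(diag(res$cov))
  tstat <- res$beta / se
  pval <- 2 * stats::pnorm(-abs(tstat))
  coefs <- data.frame(term = colnames(X), estimate = res$beta, se = se,
                      t = tstat, p = pval, row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 converged = res$converged && method == "mle",
                 iterations = res$iter, method = method,
                 ridge_used = if (method == "ridge") ridge else 0,
                 fitted = res$p_hat, levels = yb$levels, n = n),
            class = "binomial_lr")
}

# Firth's bias-reduced logistic regression: Newton iterations on the
# Jeffreys-penalized score U*(b) = X'(y - p + h (1/2 - p)) with h the hat
# values of the weighted design. Estimates are finite even under complete
# separation; SEs come from the penalized information at the optimum.
firth_logistic <- function(X, y, tol = 1e-8, max_iter = 200L) {
  beta <- numeric(ncol(X))
  converged <- FALSE; iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    inv <- tryCatch(solve(info), error = function(e) MASS::ginv(info))
    h <- rowSums((XW %*% inv) * XW)
    delta <- drop(inv %*% crossprod(X, y - p + h * (0.5 - p)))
    # step-halving guard against overshoot far from the optimum
    if ((m <- max(abs(delta))) > 5) delta <- delta * 5 / m
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  p_hat <- stats::plogis(drop(X %*% beta))
  w <- pmax(p_hat * (1 - p_hat), 1e-10)
  covb <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e)
    MASS::ginv(crossprod(X * sqrt(w))))
  list(beta = stats::setNames(beta, colnames(X)), cov = covb, p_hat = p_hat,
       converged = converged, iter = iter, ok = TRUE)
}

binary_response <- function(y) {
  if (is.factor(y) || is.character(y)) {
    f <- factor(y)
    if (nlevels(f) != 2L) stopf("y must have exactly 2 classes, found %d", nlevels(f))
    list(y01 = as.integer(f == levels(f)[[2]]), levels = levels(f))
  } else {
    v <- as.numeric(y)
    if (!all(v %in% c(0, 1))) stopf("numeric y must be 0/1")
    list(y01 = as.integer(v), levels = c("0", "1"))
  }
}

irls_logistic <- function(X, y, lambda, tol, max_iter) {
  K1 <- ncol(X)
  beta <- numeric(K1)
  pen <- diag(c(0, rep(lambda, K1 - 1L)), K1)
  dev_old <- Inf; converged <- FALSE; iter <- 0L; ok <- TRUE
  p_hat <- rep(0.5, nrow(X))
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p_hat <- stats::plogis(eta)
    w <- pmax(p_hat * (1 - p_hat), 1e-10)
    z <- eta + (y - p_hat) / w
    XtW <- t(X * w)
    H <- XtW %*% X + pen
    beta_new <- tryCatch(drop(solve(H, XtW %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) { ok <- FALSE; break }
    beta <- beta_new
    mu <- stats::plogis(drop(X %*% beta))
    dev <- -2 * sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300))) +
      lambda * sum(beta[-1L]^2)
    if (is.finite(dev_old) && abs(dev_old - dev) < tol) { converged <- TRUE; dev_old <- dev; break }
    dev_old <- dev
  }
  p_hat <- stats::plogis(drop(X %*% beta))
  w <- pmax(p_hat * (1 - p_hat), 1e-10)
  info <- t(X * w) %*% X + pen
  covb <- tryCatch(solve(info), error = function(e) {
    ok <<- FALSE
    MASS::ginv(info)
  })
  list(beta = stats::setNames(drop(beta), colnames(X)), cov = covb, p_hat = p_hat,
       converged = converged, iter = iter, ok = ok)
}

#' @export
print.binomial_lr <- function(x, ...) {
  cat(sprintf("Binomial logistic fit: %d coefficients + intercept, n = %d\n",
              nrow(x$coefficients) - 1L, x$n))
  cat(sprintf("  method: %s (%d iterations)%s\n", x$method, x$iterations,
              if (x$method != "mle") " [separation/non-convergence fallback]" else ""))
  stats::printCoefmat(as.matrix(x$coefficients[, c("estimate", "se", "t", "p")]),
                      P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Select significant principal components by Wald p-value
#'
#' Keeps the predictors whose coefficient p-value falls strictly below
#' `alpha`; the intercept is never selected and an empty selection is
#' allowed. Can be applied to a fitted [fit_binomial_lr()] model or directly
#' to a numeric vector of p-values (one per component).
#'
#' @param fit A `binomial_lr` object or numeric p-value vector.
#' @param alpha Significance level (default 0.05).
#' @return A `pc_selection` object: `$selected` (integer column indices into
#'   the score matrix), `$alpha`, `$p` (the p-values examined).
#' @export
select_significant <- function(fit, alpha = 0.05) {
  if (inherits(fit, "binomial_lr")) {
    p <- fit$coefficients$p[-1L]           # drop intercept
  } else if (is.numeric(fit)) {
    p <- as.numeric(fit)
  } else stopf("fit must be a binomial_lr object or a numeric p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0,1]")
  structure(list(selected = which(p < alpha), alpha = alpha, p = p),
            class = "pc_selection")
}

#' @export
print.pc_selection <- function(x, ...) {
  cat(sprintf("<pc_selection %d/%d components at alpha=%g>\n",
              length(x$selected), length(x$p), x$alpha))
  invisible(x)
}
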