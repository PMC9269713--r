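test_that("PCA recovers a diagonal covariance exactly", {
  x <- diag_cov_data(4, 1)
  b <- fit_pca(x)
  expect_equal(b$eigenvalues, c(4, 1))
  expect_equal(b$rotation[, 1], c(1, 0))      # sign fixed positive
  expect_equal(abs(b$rotation[, 2]), c(0, 1))
  expect_error(fit_pca(x[1, , drop = FALSE]), "at least 2")
})

test_that("eigenvalues conserve the covariance trace and match the SVD oracle", {
  set.seed(42)
  for (dims in list(c(20, 8), c(50, 10))) {
    x <- matrix(rnorm(prod(dims)), dims[[1]], dims[[2]])
    b <- fit_pca(x)
    expect_lt(abs(sum(b$eigenvalues) - sum(diag(cov(x)))), 1e-8)
    sv <- svd(scale(x, scale = FALSE))
    expect_lt(max(abs(b$eigenvalues - sv$d^2 / (dims[[1]] - 1))), 1e-8)
    for (j in seq_len(dims[[2]])) {           # directions agree up to sign
      expect_lt(min(sum(abs(b$rotation[, j] - sv$v[, j])),
                    sum(abs(b$rotation[, j] + sv$v[, j]))), 1e-6)
    }
  }
})

test_that("the wide-matrix branch solves the same eigenproblem", {
  set.seed(7)
  x <- matrix(rnorm(10 * 30), 10, 30)         # p > n
  b <- fit_pca(x)
  sv <- svd(scale(x, scale = FALSE))
  expect_lt(max(abs(b$eigenvalues[1:9] - sv$d[1:9]^2 / 9)), 1e-8)
  for (j in 1:9) {
    expect_lt(min(sum(abs(b$rotation[, j] - sv$v[, j])),
                  sum(abs(b$rotation[, j] + sv$v[, j]))), 1e-6)
  }
  expect_lt(max(abs(crossprod(b$rotation) - diag(ncol(b$rotation)))), 1e-8)
})

test_that("class-wise PCA concatenates per-class blocks in label order", {
  set.seed(11)
  x <- rbind(matrix(rnorm(60 * 6), 60, 6), matrix(rnorm(60 * 6), 60, 6))
  y <- rep(c("benign", "malignant"), each = 60)
  b <- fit_classwise_pca(x, y, k_per_class = 3)
  expect_equal(b$K, 6L)
  expect_equal(b$class_tag, rep(c("benign", "malignant"), each = 3))
  expect_equal(b$mode, "per_class")
  # same distribution in both classes: leading eigenvalues agree
  expect_lt(abs(b$eigenvalues[[1]] - b$eigenvalues[[4]]) / b$eigenvalues[[1]], 0.5)
  expect_error(fit_classwise_pca(x[c(1, 61:120), ], y[c(1, 61:120)], 2),
               "fewer than 2")
})

test_that("class-wise directions track each class's major axis", {
  set.seed(13)
  a1 <- c(1, 0, 0, 0); a2 <- c(0, 0, 0, 1)
  x1 <- matrix(rnorm(200), 50, 4) %*% diag(0.1, 4) + outer(rnorm(50, sd = 3), a1)
  x2 <- matrix(rnorm(200), 50, 4) %*% diag(0.1, 4) + outer(rnorm(50, sd = 3), a2)
  b <- fit_classwise_pca(rbind(x1, x2), rep(c("a", "b"), each = 50), 1)
  expect_gt(abs(sum(b$rotation[, 1] * a1)), 0.99)
  expect_gt(abs(sum(b$rotation[, 2] * a2)), 0.99)
})

test_that("projection centers training scores and diagonalizes their covariance", {
  set.seed(3)
  x <- matrix(rnorm(80 * 10), 80, 10) %*% diag(seq(3, 0.5, length.out = 10))
  b <- fit_pca(x)
  s <- project_pca(x, b, K = 6)
  expect_lt(max(abs(colMeans(s))), 1e-8)
  cs <- cov(s)
  expect_lt(max(abs(cs - diag(b$eigenvalues[1:6]))) / b$eigenvalues[[1]], 1e-6)
  # a sample at the mean scores zero
  mu <- matrix(colMeans(x), 1)
  expect_lt(max(abs(project_pca(mu, b, K = 6))), 1e-10)
  expect_error(project_pca(x[, 1:5], b), "does not match")
})

test_that("retained energy is normalized, monotone and exact on diagonals", {
  b <- fit_pca(diag_cov_data(3, 1))
  expect_equal(retained_energy(b, 1), 0.75)
  expect_equal(retained_energy(b, 2), 1.0)
  set.seed(5)
  b2 <- fit_pca(matrix(rnorm(200), 20, 10))
  curve <- vapply(1:10, function(k) retained_energy(b2, k), numeric(1))
  expect_true(all(diff(curve) >= -1e-12))
  expect_equal(curve[[10]], 1.0)
  expect_error(retained_energy(b2, 11), "between 1 and")
})
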