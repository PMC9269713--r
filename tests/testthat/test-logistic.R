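test_that("a symmetric design forces a null coefficient", {
  x <- matrix(c(-1, 1, -1, 1), ncol = 1)
  f <- fit_binomial_lr(x, c(0, 1, 1, 0))
  expect_equal(f$coefficients$estimate[[2]], 0, tolerance = 1e-10)
  expect_equal(f$coefficients$t[[2]], 0, tolerance = 1e-10)
  expect_equal(f$coefficients$p[[2]], 1, tolerance = 1e-10)
})

test_that("the IRLS fit matches the glm maximum-likelihood oracle", {
  set.seed(99)
  worst <- c(est = 0, se = 0, p = 0)
  for (rep in 1:25) {
    n <- sample(30:80, 1); k <- sample(1:4, 1)
    x <- matrix(rnorm(n * k), n, k)
    y <- rbinom(n, 1, plogis(x %*% rnorm(k, sd = 0.8)))
    if (length(unique(y)) < 2) next
    f <- fit_binomial_lr(x, y, tol = 1e-12)
    if (f$method != "mle") next                 # oracle applies to the MLE path
    g <- glm(y ~ x, family = binomial, control = glm.control(epsilon = 1e-12))
    sg <- summary(g)$coefficients
    worst <- pmax(worst, c(max(abs(f$coefficients$estimate - coef(g))),
                           max(abs(f$coefficients$se - sg[, 2])),
                           max(abs(f$coefficients$p - sg[, 4]))))
  }
  expect_lt(worst[["est"]], 1e-6)
  expect_lt(worst[["se"]], 1e-6)
  expect_lt(worst[["p"]], 1e-6)
})

test_that("coefficient records follow the score columns plus an intercept", {
  set.seed(4)
  x <- matrix(rnorm(120 * 50), 120, 50)
  colnames(x) <- sprintf("PC%d", 1:50)
  f <- fit_binomial_lr(x, rbinom(120, 1, 0.5))
  expect_equal(nrow(f$coefficients), 51L)
  expect_equal(f$coefficients$term[[1]], "(Intercept)")
  expect_equal(f$coefficients$term[-1], sprintf("PC%d", 1:50))
  expect_true(all(f$coefficients$se > 0))
  expect_true(all(f$coefficients$p >= 0 & f$coefficients$p <= 1))
  # t carries the sign of the estimate
  expect_equal(sign(f$coefficients$t), sign(f$coefficients$estimate))
})

test_that("degenerate inputs are rejected with clear errors", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_binomial_lr(x, rep(1, 10)), "both classes")
  expect_error(fit_binomial_lr(matrix(rnorm(100), 5, 20), c(0, 1, 0, 1, 0)),
               "more samples")
})

test_that("separated data falls back to a finite Firth fit", {
  x <- matrix(c(rnorm(25, -3), rnorm(25, 3)), ncol = 1)
  y <- rep(c(0, 1), each = 25)
  f <- fit_binomial_lr(x, y)
  expect_equal(f$method, "firth")
  expect_false(f$converged)
  expect_true(all(is.finite(f$coefficients$estimate)))
  expect_true(all(is.finite(f$coefficients$se)))
  expect_lt(f$coefficients$p[[2]], 0.05)      # the separating direction is flagged
})

test_that("Wald selection keeps exactly the sub-alpha components", {
  tab <- table1_fixture()
  sel <- select_significant(tab$p, alpha = 0.05)
  expect_setequal(sel$selected, which(tab$p < 0.05))
  expect_true(1L %in% sel$selected)            # p = 5.14e-15
  expect_false(8L %in% sel$selected)           # p = 0.995623
  expect_length(select_significant(rep(1, 10))$selected, 0L)
  expect_length(select_significant(tab$p, alpha = 1)$selected, nrow(tab))

  set.seed(21)
  x <- matrix(rnorm(300), 100, 3)
  f <- fit_binomial_lr(x, rbinom(100, 1, plogis(2 * x[, 1])))
  s <- select_significant(f)
  expect_setequal(s$selected, which(f$coefficients$p[-1] < 0.05))
})
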