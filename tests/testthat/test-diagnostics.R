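test_that("pairwise correlations match the exact t-transform formula", {
  set.seed(8)
  x <- matrix(rnorm(30 * 6), 30, 6)
  rep <- pairwise_correlation(x)
  expect_equal(diag(rep$r), rep(1, 6))
  expect_equal(rep$r, t(rep$r))
  # oracle: direct formula and cor.test on every pair
  for (k in seq_len(nrow(rep$pairs))) {
    i <- rep$pairs$i[[k]]; j <- rep$pairs$j[[k]]
    r <- cor(x[, i], x[, j])
    tt <- r * sqrt((30 - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tt), df = 28)
    expect_lt(abs(rep$pairs$r[[k]] - r), 1e-10)
    expect_lt(abs(rep$pairs$p[[k]] - p), 1e-10)
    expect_lt(abs(rep$pairs$p[[k]] - cor.test(x[, i], x[, j])$p.value), 1e-10)
  }
})

test_that("duplicated columns are flagged as perfect collinearity", {
  set.seed(12)
  x <- cbind(a = rnorm(25), b = rnorm(25))
  x <- cbind(x, c = x[, 1])
  rep <- pairwise_correlation(x)
  k <- which(rep$pairs$i == 1 & rep$pairs$j == 3)
  expect_equal(rep$pairs$r[[k]], 1, tolerance = 1e-12)
  expect_lt(rep$pairs$p[[k]], 1e-12)
  expect_error(pairwise_correlation(x[1:2, ]), "at least 3")
})

test_that("constant columns are excluded and counted", {
  set.seed(2)
  x <- cbind(matrix(rnorm(60), 20, 3), konst = rep(1, 20))
  rep <- suppressMessages(pairwise_correlation(x))
  expect_equal(rep$n_constant_excluded, 1L)
  expect_equal(ncol(rep$r), 3L)
  expect_equal(sum(rep$histogram), nrow(rep$pairs))
})

test_that("p-value histograms bin correctly with a right-closed last bin", {
  expect_equal(pvalue_histogram(rep(0.05, 7)), c(7L, rep(0L, 9)))
  expect_equal(pvalue_histogram(seq(0.05, 0.95, by = 0.1)), rep(1L, 10))
  expect_equal(pvalue_histogram(c(0, 1)), c(1L, rep(0L, 8), 1L))
  expect_error(pvalue_histogram(c(0.5, 1.2)), "lie in")
})

test_that("planted collinearity piles the p-value mass into the first bin", {
  # one dominant factor loading on every feature: the global collinearity
  # pattern deep-feature matrices show
  sim <- simulate_features(n = 60, p = 40, r = 1, n_informative = 1,
                           load = 1.2, sigma = 0.3, seed = 44)
  rep <- pairwise_correlation(sim$x)
  expect_gt(rep$frac_p_below_0.1, 0.5)
  expect_gt(rep$histogram[[1]] / sum(rep$histogram), 0.5)
  # and the within-group feature correlations are strong
  cg <- cor(sim$x[, 1:6])
  expect_gt(min(cg[upper.tri(cg)]), 0.9)
})

test_that("independent features give approximately uniform p-values", {
  sim <- simulate_features(n = 200, p = 40, r = 40, n_informative = 1,
                           load = 0, sigma = 1, seed = 77)
  rep <- pairwise_correlation(sim$x)
  expect_gte(nrow(rep$pairs), 500L)
  ks <- suppressWarnings(ks.test(rep$pairs$p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  # pure-noise design: columns essentially uncorrelated at n large
  sim2 <- simulate_features(n = 1000, p = 20, r = 20, n_informative = 1,
                            load = 0, sigma = 1, seed = 78)
  cm <- cor(sim2$x)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.15)
})
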