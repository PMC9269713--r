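test_that("lrpca recovers a planted informative subspace", {
  sim <- simulate_features(n = 520, seed = 123)
  tr <- 1:400; te <- 401:520
  red <- lr_pca_reduce(sim$x[tr, ], sim$y[tr], sim$x[te, ],
                       mode = "pooled", K = 50)
  sel <- red$selection$selected
  expect_gte(length(sel), 3L)
  ang <- max_principal_angle(red$basis$rotation[, sel, drop = FALSE],
                             sim$truth$directions)
  expect_lt(ang, 10)
  # downstream linear classifier on the selected scores separates the classes
  fit <- MASS::lda(as.matrix(red$train), grouping = sim$y[tr])
  acc <- mean(predict(fit, as.matrix(red$other))$class == sim$y[te])
  expect_gt(acc, 0.9)
})

test_that("alpha = 1 keeps every component and the transform is deterministic", {
  sim <- simulate_features(n = 150, p = 16, r = 4, n_informative = 2, seed = 5)
  red <- lr_pca_reduce(sim$x, sim$y, sim$x, mode = "pooled", K = 10, alpha = 1)
  expect_equal(ncol(red$train), 10L)
  expect_identical(unname(red$train), unname(red$other))
  again <- predict(red$fit, sim$x, type = "selected")
  expect_identical(unname(again), unname(red$train))
})

test_that("the fitted transform never sees the held-out rows", {
  sim <- simulate_features(n = 220, p = 16, r = 4, n_informative = 2, seed = 9)
  tr <- 1:150
  fit1 <- lrpca(sim$x[tr, ], sim$y[tr], K = 10)
  # perturbing other rows must not change the training fit or its transform
  x2 <- sim$x; x2[151:220, ] <- x2[151:220, ] * 5 + 7
  fit2 <- lrpca(x2[tr, ], sim$y[tr], K = 10)
  expect_identical(fit1$basis$rotation, fit2$basis$rotation)
  expect_identical(predict(fit1, sim$x[151:220, ]) ,
                   predict(fit2, sim$x[151:220, ]))
})

test_that("pooled PC scores are decorrelated, removing multicollinearity", {
  sim <- simulate_features(n = 300, p = 40, r = 8, n_informative = 3, seed = 31)
  fit <- lrpca(sim$x, sim$y, mode = "pooled", K = 30)
  cm <- cor(fit$scores)
  expect_lt(max(abs(cm[upper.tri(cm)])), 1e-6)
})

test_that("per-class mode builds ceiling(K/2) components per class", {
  sim <- simulate_features(n = 200, p = 24, r = 4, n_informative = 2, seed = 17)
  fit <- lrpca(sim$x, sim$y, mode = "per_class", K = 10)
  expect_equal(fit$K, 10L)
  meta <- attr(fit$scores, "column_meta")
  expect_equal(as.integer(table(meta$class_tag)), c(5L, 5L))
  expect_s3_class(fit, "lrpca")
  expect_equal(length(coef(fit)), 11L)
})

test_that("lrpca methods print, summarize and predict coherently", {
  sim <- simulate_features(n = 150, p = 16, r = 4, n_informative = 2, seed = 2)
  fit <- lrpca(sim$x, sim$y, K = 8)
  expect_output(print(fit), "LR-PCA")
  sm <- summary(fit)
  expect_equal(nrow(sm$table), 9L)
  expect_output(print(sm), "components selected")
  pr <- predict(fit, sim$x, type = "response")
  expect_true(all(pr >= 0 & pr <= 1))
  cl <- predict(fit, sim$x, type = "class")
  expect_setequal(levels(cl), levels(sim$y))
  expect_gt(mean(cl == sim$y), 0.8)
})
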