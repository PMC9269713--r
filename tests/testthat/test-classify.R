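test_that("stratified 70/15/15 splits hit the global and per-class sizes", {
  y <- rep(c("benign", "malignant"), each = 50)
  plan <- make_splits(y, seed = 1)
  expect_length(plan$train, 70L)
  expect_length(plan$validation, 15L)
  expect_length(plan$test, 15L)
  all_idx <- c(plan$train, plan$validation, plan$test)
  expect_setequal(all_idx, 1:100)
  expect_length(all_idx, 100L)                # disjoint and exhaustive
  for (set in list(plan$train, plan$validation, plan$test)) {
    counts <- table(y[set])
    expect_lte(abs(counts[[1]] - counts[[2]]), 1)
  }
})

test_that("splits are deterministic in the seed and folds partition train+val", {
  y <- rep(c("a", "b"), times = c(40, 60))
  p1 <- make_splits(y, seed = 7)
  p2 <- make_splits(y, seed = 7)
  expect_identical(p1, p2)
  p3 <- make_splits(y, seed = 8)
  expect_false(identical(p1$train, p3$train))
  tv <- sort(c(p1$train, p1$validation))
  expect_setequal(as.integer(names(p1$fold)), tv)
  expect_setequal(unique(p1$fold), 1:5)
  expect_error(make_splits(rep(c("a", "b"), times = c(3, 97))), "at least 5")
})

separable_scores <- function(n_per_class = 30, d = 4, gap = 8, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = gap), ncol = d))
  colnames(x) <- sprintf("PC%d", seq_len(d))
  list(x = x, y = factor(rep(c("benign", "malignant"), each = n_per_class)))
}

test_that("every classifier family solves a linearly separable problem", {
  tr <- separable_scores(seed = 1); va <- separable_scores(seed = 2)
  bank <- train_bank(tr$x, tr$y, va$x, va$y, seed = 0)
  expect_setequal(bank$validation$family, mammocad::bank_families())
  expect_true(all(bank$validation$val_accuracy == 1))
  te <- separable_scores(seed = 3)
  for (fam in names(bank$models)) {
    ev <- evaluate_model(bank$models[[fam]], te$x, te$y, positive = "malignant")
    expect_equal(ev$metrics$Acc, 100)
    expect_equal(ev$metrics$AUC, 100)
  }
  expect_error(train_bank(tr$x, tr$y, va$x, va$y, families = "boosting"),
               "unknown classifier family")
})

test_that("the subspace-kNN ensemble is stable across its sampling seed", {
  tr <- separable_scores(40, d = 10, gap = 2, seed = 4)
  va <- separable_scores(40, d = 10, gap = 2, seed = 5)
  te <- separable_scores(40, d = 10, gap = 2, seed = 6)
  accs <- vapply(c(0, 99), function(s) {
    bank <- train_bank(tr$x, tr$y, va$x, va$y,
                       families = "ensemble_subspace_knn", seed = s)
    evaluate_model(bank$models[[1]], te$x, te$y, positive = "malignant")$metrics$Acc
  }, numeric(1))
  expect_lte(abs(accs[[1]] - accs[[2]]), 2)
})

test_that("classifier scores produce sensible ROC output on noisy data", {
  tr <- separable_scores(50, d = 3, gap = 1.5, seed = 7)
  va <- separable_scores(50, d = 3, gap = 1.5, seed = 8)
  te <- separable_scores(80, d = 3, gap = 1.5, seed = 9)
  bank <- train_bank(tr$x, tr$y, va$x, va$y, seed = 1)
  for (fam in names(bank$models)) {
    ev <- evaluate_model(bank$models[[fam]], te$x, te$y, positive = "malignant")
    expect_gt(ev$metrics$AUC, 80)             # scores must rank the positive class
    expect_equal(ev$roc$fpr[[1]], 0)
    expect_true(all(diff(ev$roc$fpr) >= -1e-12))
  }
  expect_error(evaluate_model(bank$models[[1]], te$x[0, ], te$y[0]), "empty test")
})

test_that("cross-validation refits the reduction per fold and averages", {
  sim <- simulate_features(n = 200, p = 16, r = 4, n_informative = 2, seed = 3)
  plan <- make_splits(sim$y, seed = 2)
  cv <- cross_validate(sim$x, sim$y, plan, mode = "pooled", K = 10,
                       families = "knn", seed = 5)
  expect_length(cv$folds, 5L)
  expect_gt(cv$mean[["Acc"]], 85)

  # label permutation: performance collapses to chance
  set.seed(6)
  yperm <- sample(sim$y)
  plan2 <- make_splits(yperm, seed = 2)
  cv2 <- suppressMessages(cross_validate(sim$x, yperm, plan2, mode = "pooled",
                                         K = 10, families = "knn", seed = 5))
  expect_lt(abs(cv2$mean[["Acc"]] - 50), 10)
})
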