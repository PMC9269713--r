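#' Stratified train/validation/test split with CV folds
#'
#' Deterministic given `seed`. Global set sizes follow `fractions` by
#' largest-remainder apportionment; within each class the same apportionment
#' is used and reconciled with the global sizes, so per-class proportions
#' are preserved within one sample. Cross-validation folds partition the
#' train+validation indices (the test set is held out of CV entirely).
#'
#' @param labels Class labels for all samples.
#' @param fractions Train/validation/test fractions summing to 1 (default
#'   `c(0.70, 0.15, 0.15)`).
#' @param folds Number of CV folds over train+validation (default 5).
#' @param seed Integer seed.
#' @param stratified Stratify by label (default `TRUE`).
#' @return A `split_plan`: `$train`, `$validation`, `$test` (index vectors),
#'   `$fold` (named integer vector of fold ids over train+validation),
#'   `$fractions`, `$folds`, `$seed`.
#' @export
make_splits <- function(labels, fractions = c(0.70, 0.15, 0.15), folds = 5L,
                        seed = 0, stratified = TRUE) {
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L)
    stopf("fractions must be three values summing to 1")
  labels <- factor(labels)
  n <- length(labels)
  folds <- as.integer(folds)
  if (any(table(labels) < folds))
    stopf("every class needs at least %d members for %d-fold CV", folds, folds)
  global <- apportion(n, fractions)
  with_seed(seed, {
    sets <- list(integer(0), integer(0), integer(0))
    if (stratified) {
      # per-class floors, then top up cells toward the global sizes
      alloc <- t(vapply(levels(labels), function(cl) {
        floor(sum(labels == cl) * fractions)
      }, numeric(3)))
      for (s in 1:3) {
        while (sum(alloc[, s]) < global[[s]]) {
          deficit <- vapply(seq_len(nrow(alloc)), function(ci) {
            sum(labels == levels(labels)[ci]) * fractions[[s]] - alloc[ci, s]
          }, numeric(1))
          room <- rowSums(alloc) < table(labels)
          pick <- which(room)[which.max(deficit[room])]
          alloc[pick, s] <- alloc[pick, s] + 1
        }
      }
      for (ci in seq_along(levels(labels))) {
        idx <- sample(which(labels == levels(labels)[ci]))
        bounds <- cumsum(c(0, alloc[ci, ]))
        for (s in 1:3)
          sets[[s]] <- c(sets[[s]], idx[seq.int(bounds[[s]] + 1L, length.out = alloc[ci, s])])
      }
    } else {
      idx <- sample(n)
      bounds <- cumsum(c(0, global))
      for (s in 1:3) sets[[s]] <- idx[seq.int(bounds[[s]] + 1L, length.out = global[[s]])]
    }
    trainval <- sort(c(sets[[1]], sets[[2]]))
    fold <- integer(length(trainval))
    names(fold) <- trainval
    for (cl in levels(labels)) {
      members <- sample(trainval[labels[trainval] == cl])
      fold[as.character(members)] <- rep_len(seq_len(folds), length(members))
    }
    structure(list(train = sort(sets[[1]]), validation = sort(sets[[2]]),
                   test = sort(sets[[3]]), fold = fold,
                   fractions = fractions, folds = folds, seed = seed,
                   stratified = stratified, n = n),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan train=%d validation=%d test=%d folds=%d seed=%s>\n",
              length(x$train), length(x$validation), length(x$test), x$folds,
              format(x$seed)))
  invisible(x)
}

#' Names of the supported classifier families
#'
#' @return Character vector of the six family names accepted by
#'   [train_bank()], in tie-break order.
#' @export
bank_families <- function() {
  c("tree", "discriminant", "svm", "knn", "naive_bayes", "ensemble_subspace_knn")
}

#' Train the classical classifier bank
#'
#' Fits six classifier families on the training scores and tunes each over a
#' small documented grid by validation accuracy:
#'
#' * `tree`: CART ([rpart::rpart]), max depth in \{3, 5, 10, 30\};
#' * `discriminant`: linear and quadratic discriminant analysis
#'   ([MASS::lda]/[MASS::qda]);
#' * `svm`: [e1071::svm] with linear and RBF kernels, cost in
#'   \{0.1, 1, 10\}, default kernel scale;
#' * `knn`: [class::knn], k in \{1, 3, 5, 7\}, Euclidean distance;
#' * `naive_bayes`: Gaussian naive Bayes ([e1071::naiveBayes]);
#' * `ensemble_subspace_knn`: random-subspace ensemble of 30 1-NN learners,
#'   each on a random half of the feature columns, majority vote (the
#'   "subspace KNN" ensemble).
#'
#' Ties are broken by grid order (simpler setting first) and the overall
#' winner by the family order above. Classifier scores used for ROC/AUC are
#' the positive-class vote fraction (kNN and ensemble), posterior
#' probability (tree, discriminant, naive Bayes) or decision value (SVM).
#'
#' @param x_train,y_train Training scores and labels.
#' @param x_val,y_val Validation scores and labels used for tuning.
#' @param families Subset of the six family names (default: all).
#' @param positive Positive class (default: second sorted level).
#' @param seed Seed for the subspace sampling and kNN tie-breaks.
#' @return A `classifier_bank`: `$models` (named list of `cad_model`),
#'   `$validation` (data frame of family, setting, accuracy), `$best`
#'   (winning family name).
#' @export
train_bank <- function(x_train, y_train, x_val, y_val,
                       families = bank_families(), positive = NULL, seed = 0) {
  unknown <- setdiff(families, bank_families())
  if (length(unknown)) stopf("unknown classifier family: %s", paste(unknown, collapse = ", "))
  families <- bank_families()[bank_families() %in% families]
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  y_train <- factor(y_train); y_val <- factor(y_val, levels = levels(y_train))
  if (is.null(positive)) positive <- levels(y_train)[[nlevels(y_train)]]

  models <- list(); rows <- list()
  for (fam in families) {
    cands <- bank_candidates(fam, x_train, y_train, positive, seed)
    best <- NULL; best_acc <- -Inf
    for (cand in cands) {
      model <- tryCatch(cand$fit(), error = function(e) NULL)
      if (is.null(model)) next
      acc <- mean(predict_cad(model, x_val)$class == as.character(y_val))
      if (acc > best_acc) { best <- model; best_acc <- acc }
    }
    if (is.null(best)) stopf("no candidate of family '%s' could be fitted", fam)
    models[[fam]] <- best
    rows[[fam]] <- data.frame(family = fam, setting = best$setting_label,
                              val_accuracy = best_acc, stringsAsFactors = FALSE)
  }
  val_tab <- do.call(rbind, rows)
  rownames(val_tab) <- NULL
  best_fam <- val_tab$family[[which.max(val_tab$val_accuracy)]]
  structure(list(models = models, validation = val_tab, best = best_fam,
                 positive = positive, levels = levels(y_train)),
            class = "classifier_bank")
}

#' @export
print.classifier_bank <- function(x, ...) {
  cat("Classifier bank (validation accuracy):\n")
  print(x$validation, row.names = FALSE)
  cat(sprintf("winner: %s\n", x$best))
  invisible(x)
}

new_cad_model <- function(family, setting_label, predict_fun) {
  structure(list(family = family, setting_label = setting_label, predict = predict_fun),
            class = "cad_model")
}

#' @export
print.cad_model <- function(x, ...) {
  cat(sprintf("<cad_model %s [%s]>\n", x$family, x$setting_label))
  invisible(x)
}

# Every candidate returns list(class = character labels, score = numeric
# positive-class score) from predict_fun(newdata).
bank_candidates <- function(fam, x, y, positive, seed) {
  lv <- levels(y)
  switch(fam,
    tree = lapply(c(3L, 5L, 10L, 30L), function(depth) {
      list(fit = function() {
        df <- data.frame(y = y, x)
        fit <- rpart::rpart(y ~ ., data = df, method = "class",
                            control = rpart::rpart.control(maxdepth = depth,
                                                           cp = 0, xval = 0))
        new_cad_model("tree", sprintf("maxdepth=%d", depth), function(nd) {
          pr <- predict(fit, data.frame(nd), type = "prob")
          list(class = colnames(pr)[max.col(pr, ties.method = "first")],
               score = pr[, positive])
        })
      })
    }),
    discriminant = lapply(c("lda", "qda"), function(kind) {
      list(fit = function() {
        fit <- if (kind == "lda") MASS::lda(x, grouping = y) else MASS::qda(x, grouping = y)
        new_cad_model("discriminant", kind, function(nd) {
          pr <- predict(fit, nd)
          list(class = as.character(pr$class), score = pr$posterior[, positive])
        })
      })
    }),
    svm = {
      grid <- expand.grid(kernel = c("linear", "radial"), cost = c(0.1, 1, 10),
                          stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i) {
        list(fit = function() {
          fit <- e1071::svm(x, y, kernel = grid$kernel[[i]], cost = grid$cost[[i]],
                            scale = FALSE)
          # orient decision values toward the positive class
          flip <- if (fit$labels[[1]] == which(lv == positive)) 1 else -1
          new_cad_model("svm", sprintf("%s cost=%g", grid$kernel[[i]], grid$cost[[i]]),
                        function(nd) {
            pr <- predict(fit, nd, decision.values = TRUE)
            list(class = as.character(pr),
                 score = flip * drop(attr(pr, "decision.values")))
          })
        })
      })
    },
    knn = lapply(c(1L, 3L, 5L, 7L), function(k) {
      list(fit = function() {
        new_cad_model("knn", sprintf("k=%d", k), function(nd) {
          knn_vote(x, y, nd, k, positive, seed)
        })
      })
    }),
    naive_bayes = list(list(fit = function() {
      fit <- e1071::naiveBayes(x, y)
      new_cad_model("naive_bayes", "gaussian", function(nd) {
        pr <- predict(fit, nd, type = "raw")
        list(class = colnames(pr)[max.col(pr, ties.method = "first")],
             score = pr[, positive])
      })
    })),
    ensemble_subspace_knn = list(list(fit = function() {
      n_learners <- 30L
      frac <- 0.5
      subsets <- with_seed(seed + 1L, lapply(seq_len(n_learners), function(i)
        sort(sample(ncol(x), max(1L, round(frac * ncol(x)))))))
      new_cad_model("ensemble_subspace_knn",
                    sprintf("%d learners, subspace %.2f, 1-NN", n_learners, frac),
                    function(nd) {
        votes <- matrix(0, nrow(as.matrix(nd)), n_learners)
        for (i in seq_len(n_learners)) {
          cols <- subsets[[i]]
          votes[, i] <- knn_vote(x[, cols, drop = FALSE], y,
                                 as.matrix(nd)[, cols, drop = FALSE],
                                 1L, positive, seed)$score
        }
        frac_pos <- rowMeans(votes)
        cls <- ifelse(frac_pos > 0.5, positive, setdiff(lv, positive)[[1]])
        # exact .5 vote: fall back to the first learner's call
        tie <- frac_pos == 0.5
        if (any(tie)) cls[tie] <- ifelse(votes[tie, 1] >= 0.5, positive,
                                         setdiff(lv, positive)[[1]])
        list(class = cls, score = frac_pos)
      })
    })))
}

# k-NN positive-class vote fraction via class::knn.
knn_vote <- function(x, y, nd, k, positive, seed) {
  nd <- as.matrix(nd)
  pred <- with_seed(seed, class::knn(x, nd, cl = y, k = k, prob = TRUE))
  win <- attr(pred, "prob")
  score <- ifelse(as.character(pred) == positive, win, 1 - win)
  list(class = as.character(pred), score = score)
}

predict_cad <- function(model, newdata) model$predict(as.matrix(newdata))

# Mean CV accuracy per family over the plan's train+validation folds, with
# the LR-PCA reduction refit inside each fold (leakage-free). Grid settings
# are tuned on an inner stratified 80/20 split of each fold's training part.
# With use_selection = FALSE the Wald filter is bypassed and all K score
# columns feed the classifiers (an empty selection falls back to that
# anyway).
family_cv_accuracy <- function(x, y, plan, mode, K, alpha,
                               families = bank_families(), positive = NULL,
                               seed = 0, use_selection = TRUE) {
  fold_idx <- as.integer(names(plan$fold))
  acc <- matrix(NA_real_, plan$folds, length(families),
                dimnames = list(NULL, families))
  for (f in seq_len(plan$folds)) {
    hold <- fold_idx[plan$fold == f]
    fit_rows <- setdiff(fold_idx, hold)
    red <- lr_pca_reduce(x[fit_rows, , drop = FALSE], y[fit_rows],
                         x[hold, , drop = FALSE], mode = mode, K = K, alpha = alpha)
    tr <- red$train; te <- red$other
    if (!use_selection || ncol(tr) == 0L) {
      tr <- red$fit$scores
      te <- predict(red$fit, x[hold, , drop = FALSE], type = "scores")
    }
    inner <- make_splits(y[fit_rows], fractions = c(0.8, 0.2, 0), folds = 2L,
                         seed = seed + f)
    bank <- train_bank(tr[inner$train, , drop = FALSE], y[fit_rows][inner$train],
                       tr[inner$validation, , drop = FALSE],
                       y[fit_rows][inner$validation],
                       families = families, positive = positive, seed = seed + f)
    for (fam in names(bank$models))
      acc[f, fam] <- mean(predict_cad(bank$models[[fam]], te)$class ==
                            as.character(y[hold]))
  }
  colMeans(acc)
}

#' Evaluate a fitted classifier on a test set
#'
#' @param model A `cad_model` (an element of a [train_bank()] result).
#' @param x_test,y_test Test scores and labels (non-empty; both classes
#'   needed for a defined AUC).
#' @param positive Positive class.
#' @return List with `confusion` ([confusion_matrix]), `metrics`
#'   ([metric_report], AUC included) and `roc` ([roc_points] data frame, or
#'   `NULL` for a single-class test set).
#' @export
evaluate_model <- function(model, x_test, y_test, positive = NULL) {
  if (length(y_test) == 0L) stopf("cannot evaluate an empty test set")
  pr <- predict_cad(model, x_test)
  truth <- as.character(y_test)
  if (is.null(positive)) positive <- sort(unique(truth))[[length(unique(truth))]]
  metrics <- metric_report(truth, pr$class, scores = pr$score, positive = positive)
  roc <- if (length(unique(truth)) > 1L) roc_points(pr$score, truth, positive) else NULL
  list(confusion = metrics$confusion, metrics = metrics, roc = roc)
}

#' Cross-validated end-to-end pipeline evaluation
#'
#' Runs the full LR-PCA reduction plus classifier bank inside each CV fold:
#' for fold `f`, the basis, logistic selection and classifiers are fitted on
#' the other folds' samples only and evaluated on fold `f`, so no held-out
#' sample ever influences its own feature selection. The bank is tuned on an
#' internal stratified 80/20 split of the fold's training part. Reports are
#' averaged over folds.
#'
#' @param x Feature matrix (all train+validation samples are drawn from it
#'   via `plan`).
#' @param y Labels.
#' @param plan A [make_splits()] plan; its `$fold` assignment defines the
#'   folds and its test set stays untouched.
#' @param mode,K,alpha LR-PCA settings, see [lrpca()].
#' @param families Classifier families, see [train_bank()].
#' @param positive Positive class.
#' @param seed Seed for the per-fold bank tuning.
#' @return A `cv_result`: `$folds` (per-fold [metric_report]s of each fold's
#'   winning model), `$mean` and `$sd` (named metric vectors over folds),
#'   `$winners` (per-fold winning family).
#' @export
cross_validate <- function(x, y, plan, mode = "pooled", K = 50L, alpha = 0.05,
                           families = bank_families(), positive = NULL, seed = 0) {
  x <- as.matrix(x); y <- factor(y)
  fold_idx <- as.integer(names(plan$fold))
  reports <- list(); winners <- character(0)
  for (f in seq_len(plan$folds)) {
    hold <- fold_idx[plan$fold == f]
    fit_rows <- setdiff(fold_idx, hold)
    red <- lr_pca_reduce(x[fit_rows, , drop = FALSE], y[fit_rows],
                         x[hold, , drop = FALSE], mode = mode, K = K, alpha = alpha)
    tr <- red$train; te <- red$other
    if (ncol(tr) == 0L) {          # empty selection: fall back to all K scores
      message(sprintf("fold %d: empty selection, using all %d components", f, red$fit$K))
      tr <- red$fit$scores
      te <- predict(red$fit, x[hold, , drop = FALSE], type = "scores")
    }
    inner <- make_splits(y[fit_rows], fractions = c(0.8, 0.2, 0), folds = 2L,
                         seed = seed + f)
    bank <- train_bank(tr[inner$train, , drop = FALSE], y[fit_rows][inner$train],
                       tr[inner$validation, , drop = FALSE], y[fit_rows][inner$validation],
                       families = families, positive = positive, seed = seed + f)
    ev <- evaluate_model(bank$models[[bank$best]], te, y[hold], positive = positive)
    reports[[f]] <- ev$metrics
    winners[[f]] <- bank$best
  }
  keys <- c("Acc", "SE", "SP", "PRE", "FNR", "FPR", "AUC", "MCC", "F1")
  tab <- vapply(reports, function(r) unlist(r[keys]), numeric(length(keys)))
  structure(list(folds = reports, winners = winners,
                 mean = rowMeans(tab, na.rm = TRUE),
                 sd = apply(tab, 1L, stats::sd, na.rm = TRUE)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, digits = 2, ...) {
  cat(sprintf("Cross-validation over %d folds (winners: %s)\n",
              length(x$folds), paste(x$winners, collapse = ", ")))
  out <- rbind(mean = x$mean, sd = x$sd)
  print(round(out, digits))
  invisible(x)
}
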