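#' Prepare an ROI sample set from annotated grayscale images
#'
#' Runs the data-preparation stage end to end: parse annotations, extract
#' ROIs from each referenced image (non-overlapping tiles for circle
#' annotations, whole-box resize for boxes), augment by exact rotations
#' (and optional flips), and write one PNG per sample plus a tab-separated
#' manifest (`sample_id`, `label`, `source`, `transform`).
#'
#' @param images_dir Directory holding `<image_id>.png` or `<image_id>.pgm`.
#' @param annotations Annotation file path, or a parsed
#'   [read_annotations()] data frame.
#' @param dialect Annotation dialect (when `annotations` is a path).
#' @param mode Extraction mode, `NULL` = per-geometry default.
#' @param side ROI side (default 32).
#' @param rotations,flips Augmentation settings, see [augment_rois()].
#' @param out_dir Output directory.
#' @return The manifest data frame, invisibly; written to
#'   `out_dir/manifest.tsv` alongside the sample PNGs.
#' @export
prepare_dataset <- function(images_dir, annotations, dialect = "minimias_info",
                            mode = NULL, side = 32L,
                            rotations = c(0, 90, 180, 270), flips = FALSE,
                            out_dir) {
  ann <- if (is.character(annotations)) read_annotations(annotations, dialect) else annotations
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, , drop = FALSE]
    if (a$geometry == "none") next   # normal-tissue records carry no geometry
    img_path <- Filter(file.exists,
                       file.path(images_dir, paste0(a$image_id, c(".png", ".pgm"))))
    if (length(img_path) == 0L) stopf("no image found for '%s' in %s", a$image_id, images_dir)
    image <- read_gray_image(img_path[[1]])
    rois <- extract_rois(image, a, mode = mode, side = side)
    if (length(rois) == 0L) {
      message(sprintf("no ROI fits annotation %d (%s); skipped", i, a$image_id))
      next
    }
    samples <- augment_rois(rois, rotations = rotations, flips = flips)
    for (s in samples) {
      id <- sprintf("%s_%03d_%s", s$source$image_id, length(rows) + 1L,
                    s$source$transform)
      write_image_png(s$pixels, file.path(out_dir, paste0(id, ".png")))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = id, label = s$label,
        source = sprintf("%s@%s,%s", s$source$image_id,
                         format(s$source$offset[[1]]), format(s$source$offset[[2]])),
        transform = s$source$transform, stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), label = character(0),
               source = character(0), transform = character(0))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Extract features for a prepared sample set
#'
#' Reads the samples listed in a manifest, applies the pseudo-color mapping
#' at native resolution, resizes to the backbone's input side where needed,
#' and extracts the feature matrix.
#'
#' @param manifest_path Path to a `manifest.tsv` written by
#'   [prepare_dataset()] or [write_roi_dataset()]; sample PNGs must sit in
#'   the same directory.
#' @param backbone,weights_source,seed,fallback_dim See
#'   [extract_features()].
#' @param pseudo_color Apply the three-channel pseudo-color mapping
#'   (default); `FALSE` replicates the grayscale plane.
#' @return List with `features` (matrix) and `labels` (factor, manifest
#'   order).
#' @export
extract_from_manifest <- function(manifest_path, backbone = "fallback",
                                  weights_source = "random_seeded", seed = 0,
                                  fallback_dim = 256L, pseudo_color = TRUE) {
  man <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  spec <- backbone_registry(backbone)
  imgs <- stats::setNames(vector("list", nrow(man)), man$sample_id)
  for (i in seq_len(nrow(man))) {
    px <- read_gray_image(file.path(dir, paste0(man$sample_id[[i]], ".png")))
    img <- if (pseudo_color) to_pseudo_color(px) else to_pseudo_color_stackgray(px)
    if (!is.na(spec$input_side)) img <- resize_for_backbone(img, spec$input_side)
    imgs[[i]] <- img
  }
  list(features = extract_features(imgs, backbone, weights_source = weights_source,
                                   seed = seed, fallback_dim = fallback_dim),
       labels = factor(man$label))
}

#' Run the full CAD experiment on an in-memory ROI set
#'
#' The complete desk protocol: pseudo-color each patch, extract features
#' with the chosen backbone, split 70/15/15 stratified, fit the LR-PCA
#' reduction on the training rows, tune each classifier family's settings
#' on the validation rows, pick the winning configuration by 5-fold
#' cross-validation over train+validation (the reduction refit inside each
#' fold), and report the winner's metrics on the held-out test rows.
#'
#' Two pipeline variants compete in the CV: classifiers on the
#' Wald-selected score columns and classifiers on all `K` columns. On
#' strongly separated data the Wald filter's statistics are unreliable
#' (see the package vignette) and can keep a handful of weak components;
#' validating the filter itself by CV keeps the experiment honest about
#' whether the selection helps. CV winner selection also matters for the
#' family choice: with a small validation set several families routinely
#' tie at 100% and the tie order would otherwise decide.
#'
#' @param images List of grayscale patches (e.g. `simulate_rois()$images`).
#' @param labels Binary labels, one per patch.
#' @param backbone Feature extractor (default `"fallback"`, which needs no
#'   pretrained weights).
#' @param mode,K,alpha LR-PCA settings.
#' @param families Classifier families, see [train_bank()].
#' @param fractions Split fractions.
#' @param fallback_dim Fallback extractor dimension.
#' @param pseudo_color Apply the pseudo-color mapping (default `TRUE`).
#' @param seed Seed controlling extraction, split and bank tuning.
#' @return List with `features`, `plan`, `reduction` (the `lrpca` fit),
#'   `bank`, `cv_accuracy` (per-family CV accuracy for both variants),
#'   `winner`, `used_selection` (whether the winning pipeline applies the
#'   Wald filter), `evaluation` (test-set [evaluate_model()] result of the
#'   winning model) and `test_accuracy` (percent).
#' @export
cad_experiment <- function(images, labels, backbone = "fallback",
                           mode = "per_class", K = 50L, alpha = 0.05,
                           families = bank_families(),
                           fractions = c(0.70, 0.15, 0.15),
                           fallback_dim = 256L, pseudo_color = TRUE, seed = 0) {
  labels <- factor(labels)
  spec <- backbone_registry(backbone)
  imgs <- lapply(images, function(px) {
    img <- if (pseudo_color) to_pseudo_color(px) else to_pseudo_color_stackgray(px)
    if (!is.na(spec$input_side)) img <- resize_for_backbone(img, spec$input_side)
    img
  })
  names(imgs) <- names(images)
  feats <- extract_features(imgs, backbone, seed = seed, fallback_dim = fallback_dim)
  plan <- make_splits(labels, fractions = fractions, seed = seed)
  red <- lrpca(feats[plan$train, , drop = FALSE], labels[plan$train],
               mode = mode, K = K, alpha = alpha)
  n_sel <- length(red$selection$selected)
  cv_sel <- if (n_sel > 0L)
    family_cv_accuracy(feats, labels, plan, mode = mode, K = K, alpha = alpha,
                       families = families, seed = seed, use_selection = TRUE)
  cv_all <- family_cv_accuracy(feats, labels, plan, mode = mode, K = K,
                               alpha = alpha, families = families, seed = seed,
                               use_selection = FALSE)
  # prefer the selected (smaller) pipeline on ties
  use_selection <- n_sel > 0L && max(cv_sel) >= max(cv_all)
  cv_acc <- if (use_selection) cv_sel else cv_all
  winner <- names(cv_acc)[[which.max(cv_acc)]]

  transform <- function(rows) {
    if (use_selection) predict(red, feats[rows, , drop = FALSE], type = "selected")
    else predict(red, feats[rows, , drop = FALSE], type = "scores")
  }
  bank <- train_bank(transform(plan$train), labels[plan$train],
                     transform(plan$validation), labels[plan$validation],
                     families = families, seed = seed)
  ev <- evaluate_model(bank$models[[winner]], transform(plan$test),
                       labels[plan$test])
  list(features = feats, plan = plan, reduction = red, bank = bank,
       cv_accuracy = list(selected = cv_sel, all_components = cv_all),
       winner = winner, used_selection = use_selection, evaluation = ev,
       test_accuracy = ev$metrics$Acc)
}
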