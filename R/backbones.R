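#' Backbone registry
#'
#' Metadata for the supported frozen feature extractors: input side, feature
#' dimensionality at the tap point, and approximate trainable-parameter count
#' in millions. The tap point is the last fully-connected hidden layer for
#' AlexNet and VGG16 (4096 features each) and the global-average-pool output
#' for GoogLeNet (1024 features). The `fallback` extractor is a deterministic
#' seeded random projection with a configurable dimension (see
#' [fallback_extract()]) and has no fixed architecture.
#'
#' @param name Optional backbone name; if given, the single matching row is
#'   returned (unknown names are an error).
#' @return Data frame with columns `name`, `input_side`, `feature_dim`,
#'   `param_count_millions`.
#' @export
backbone_registry <- function(name = NULL) {
  reg <- data.frame(
    name = c("alexnet", "googlenet", "vgg16", "fallback"),
    input_side = c(227L, 224L, 224L, NA_integer_),
    feature_dim = c(4096L, 1024L, 4096L, 256L),
    param_count_millions = c(61, 7, 138, NA_real_),
    stringsAsFactors = FALSE)
  if (is.null(name)) return(reg)
  hit <- reg[reg$name == name, , drop = FALSE]
  if (nrow(hit) == 0L) stopf("unknown backbone '%s' (known: %s)", name,
                             paste(reg$name, collapse = ", "))
  hit
}

#' Count the trainable parameters of a backbone architecture
#'
#' The count is computed by instantiating the architecture table (layer
#' shapes, channel groups, classifier head included) and summing weight and
#' bias tensor sizes; no weights are materialized.
#'
#' @param backbone `"alexnet"`, `"googlenet"` or `"vgg16"`.
#' @return Parameter count in millions, rounded to the nearest million.
#' @export
count_parameters <- function(backbone) {
  if (identical(backbone, "fallback"))
    stopf("the fallback extractor has no fixed architecture to count")
  backbone_registry(backbone)  # validates the name
  round(cnn_param_count(cnn_architecture(backbone)) / 1e6)
}

#' Extract frozen deep features from a batch of images
#'
#' Runs each image through the named backbone up to its feature tap and
#' returns the feature matrix (one row per image, in input order). With
#' `weights_source = "random_seeded"` the weights are drawn once from a
#' seeded He-normal initialization, so the extraction is fully deterministic
#' and needs no network download; this mode exercises the exact architecture
#' and is intended for pipeline and shape testing. With `"pretrained"` a
#' serialized weight list must be supplied via `weights_file` (an RDS file
#' with one entry per layer as produced by the same layer layout).
#'
#' @param images List of pseudo-color arrays (side x side x 3) or grayscale
#'   matrices (replicated to three channels). Each must already be resized to
#'   the backbone's input side (see [resize_for_backbone()]).
#' @param backbone `"alexnet"`, `"googlenet"`, `"vgg16"` or `"fallback"`.
#' @param weights_source `"random_seeded"` (default) or `"pretrained"`.
#' @param seed Seed for the random weight initialization.
#' @param weights_file RDS path with pretrained weights (pretrained mode).
#' @param fallback_dim Feature dimension when `backbone = "fallback"`.
#' @return An n x feature_dim matrix with attributes `backbone`,
#'   `weights_source` and `seed`; row names are taken from the list names.
#' @export
extract_features <- function(images, backbone,
                             weights_source = c("random_seeded", "pretrained"),
                             seed = 0, weights_file = NULL, fallback_dim = 256L) {
  weights_source <- match.arg(weights_source)
  spec <- backbone_registry(backbone)
  if (backbone == "fallback")
    return(fallback_extract(images, dim = fallback_dim, seed = seed))
  arch <- cnn_architecture(backbone)
  if (weights_source == "pretrained") {
    if (is.null(weights_file) || !file.exists(weights_file %||% ""))
      stopf(paste0("pretrained weights for '%s' are not available locally; ",
                   "pass weights_file=<rds> or use weights_source='random_seeded' ",
                   "for offline, download-free extraction"), backbone)
    weights <- readRDS(weights_file)
  } else {
    weights <- cnn_init_weights(arch, seed = seed)
  }
  out <- matrix(NA_real_, nrow = length(images), ncol = spec$feature_dim)
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (is.matrix(img)) img <- to_pseudo_color_stackgray(img)
    out[i, ] <- cnn_forward(arch, weights, img)
  }
  finish_feature_matrix(out, images, backbone, weights_source, seed)
}

#' Deterministic offline fallback feature extractor
#'
#' Each image is bilinearly downsampled to a fixed 16 x 16 x 3 grid,
#' flattened (768 values) and projected onto `dim` features by a seeded
#' random matrix with orthonormal columns. Same seed and inputs give
#' bit-identical output, making the whole pipeline testable with no
#' pretrained weights.
#'
#' @param images List of pseudo-color arrays or grayscale matrices.
#' @param dim Output feature dimension, between 1 and 768.
#' @param seed Seed for the projection matrix.
#' @return An n x `dim` feature matrix (see [extract_features()]).
#' @export
fallback_extract <- function(images, dim = 256L, seed = 0) {
  dim <- as.integer(dim)
  if (dim < 1L) stopf("dim must be at least 1")
  grid <- 16L
  if (dim > 3L * grid * grid)
    stopf("fallback dim must be at most %d (flattened %dx%dx3 grid)", 3L * grid * grid, grid, grid)
  proj <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(3 * grid * grid * dim),
                                         3L * grid * grid, dim))))
  flat <- matrix(0, length(images), 3L * grid * grid)
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (is.matrix(img)) img <- to_pseudo_color_stackgray(img)
    small <- resize_for_backbone(img, grid)
    flat[i, ] <- as.vector(small)
  }
  finish_feature_matrix(flat %*% proj, images, "fallback", "random_seeded", seed)
}

finish_feature_matrix <- function(out, images, backbone, weights_source, seed) {
  if (anyNA(out) || any(!is.finite(out))) stopf("non-finite feature values produced")
  rn <- names(images)
  rownames(out) <- if (!is.null(rn) && all(nzchar(rn))) rn else
    sprintf("sample_%04d", seq_len(nrow(out)))
  colnames(out) <- sprintf("f%04d", seq_len(ncol(out)))
  attr(out, "backbone") <- backbone
  attr(out, "weights_source") <- weights_source
  attr(out, "seed") <- seed
  out
}

# internal accessor used by tests
fallback_projection <- function(dim = 256L, seed = 0) {
  grid <- 16L
  with_seed(seed, qr.Q(qr(matrix(stats::rnorm(3 * grid * grid * dim),
                                 3L * grid * grid, dim))))
}

#' Write / read a feature matrix as delimited text
#'
#' Tab-separated with a one-line header (`sample_id` then `f0001`...), plus a
#' JSON sidecar (`<path>.json`) recording backbone, weights source and seed.
#'
#' @param x Feature matrix from [extract_features()].
#' @param path Output path (`.tsv`).
#' @return `path` invisibly (write) or the feature matrix (read).
#' @export
write_features <- function(x, path) {
  df <- data.frame(sample_id = rownames(x) %||% sprintf("sample_%04d", seq_len(nrow(x))),
                   x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(backbone = attr(x, "backbone"), weights_source = attr(x, "weights_source"),
               seed = attr(x, "seed"), n = nrow(x), dim = ncol(x))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1L, drop = FALSE])
  rownames(x) <- df[[1L]]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    attr(x, "backbone") <- meta$backbone
    attr(x, "weights_source") <- meta$weights_source
    attr(x, "seed") <- meta$seed
  }
  x
}
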