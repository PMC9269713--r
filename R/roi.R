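#' Construct a grayscale ROI
#'
#' A `gray_roi` is a square patch of normalized intensities in `[0, 1]`
#' together with its class label and provenance (source image, offset within
#' it, and any augmentation transform applied).
#'
#' @param pixels Square numeric matrix with values in `[0, 1]`.
#' @param label Lesion class: `"normal"`, `"benign"` or `"malignant"`.
#' @param image_id Identifier of the source image.
#' @param offset Integer `(row, col)` of the patch's top-left pixel in the
#'   source image (1-based), or `NA` when not applicable.
#' @param transform Augmentation tag, `"identity"` for untransformed patches.
#' @return An object of class `gray_roi`.
#' @export
gray_roi <- function(pixels, label, image_id = NA_character_,
                     offset = c(NA_integer_, NA_integer_), transform = "identity") {
  check_intensity(pixels, "ROI")
  if (nrow(pixels) != ncol(pixels)) stopf("ROI must be square, got %dx%d", nrow(pixels), ncol(pixels))
  if (min(pixels) < 0 || max(pixels) > 1) stopf("ROI intensities must lie in [0,1]")
  label <- match.arg(label, lesion_levels())
  structure(list(pixels = pixels, side = nrow(pixels), label = label,
                 source = list(image_id = image_id, offset = offset, transform = transform)),
            class = "gray_roi")
}

#' @export
print.gray_roi <- function(x, ...) {
  cat(sprintf("<gray_roi %dx%d label=%s image=%s transform=%s>\n",
              x$side, x$side, x$label, x$source$image_id, x$source$transform))
  invisible(x)
}

#' Extract ROIs from an annotated grayscale image
#'
#' Two extraction modes are supported, matching the two annotation styles:
#'
#' * `"tile_nonoverlap"` (circle annotations): lays a row-major grid of
#'   `side` x `side` tiles over the circle's bounding square (step = `side`,
#'   so tiles never overlap) and keeps every tile whose four corners all lie
#'   inside the circle. Tiles reaching outside the image are dropped, not
#'   padded.
#' * `"whole_box_resize"` (box annotations): crops the bounding box and
#'   resizes it to `side` x `side` (bilinear, anti-aliased), returning exactly
#'   one ROI.
#'
#' Bottom-left annotation origins are converted to top-left raster coordinates
#' here, where the image height is known.
#'
#' @param image Numeric matrix in `[0, 1]`, row 1 = top raster row.
#' @param ann One-row annotation (a row of [read_annotations()] output) or a
#'   list with the same fields.
#' @param mode Extraction mode; defaults to the mode implied by the geometry.
#' @param side Tile side in pixels (default 32).
#' @return List of [gray_roi] objects (possibly empty in tile mode).
#' @export
extract_rois <- function(image, ann, mode = NULL, side = 32L) {
  check_intensity(image)
  side <- as.integer(side)
  if (side < 1L) stopf("side must be positive")
  geom <- as.character(ann$geometry)
  if (is.null(mode)) mode <- if (geom == "circle") "tile_nonoverlap" else "whole_box_resize"
  mode <- match.arg(mode, c("tile_nonoverlap", "whole_box_resize"))
  H <- nrow(image); W <- ncol(image)
  label <- as.character(ann$lesion_class)
  id <- as.character(ann$image_id)

  if (mode == "tile_nonoverlap") {
    if (geom != "circle") stopf("tile_nonoverlap requires a circle annotation")
    cx <- ann$cx; cy <- ann$cy; r <- ann$radius
    if (identical(as.character(ann$origin), "bottom_left")) cy <- H - 1 - cy  # 0-based flip
    # work in 0-based pixel coordinates; tile top-left at (x, y)
    x_anchor <- cx - r; y_anchor <- cy - r
    n_steps <- max(0L, floor((2 * r - side) / side) + 1L)
    rois <- list()
    dropped <- 0L
    if (n_steps > 0L) {
      for (gy in seq_len(n_steps) - 1L) {      # row-major: rows outer
        for (gx in seq_len(n_steps) - 1L) {
          x0 <- x_anchor + gx * side; y0 <- y_anchor + gy * side
          corners_x <- c(x0, x0 + side - 1, x0, x0 + side - 1)
          corners_y <- c(y0, y0, y0 + side - 1, y0 + side - 1)
          if (any((corners_x - cx)^2 + (corners_y - cy)^2 > r^2)) next
          ri <- round(y0) + 1L; ci <- round(x0) + 1L   # back to 1-based indices
          if (ri < 1L || ci < 1L || ri + side - 1L > H || ci + side - 1L > W) {
            dropped <- dropped + 1L
            next
          }
          px <- image[ri:(ri + side - 1L), ci:(ci + side - 1L), drop = FALSE]
          rois[[length(rois) + 1L]] <- gray_roi(px, label, id, offset = c(ri, ci))
        }
      }
    }
    if (dropped > 0L)
      message(sprintf("extract_rois: dropped %d tile(s) exceeding image bounds for %s", dropped, id))
    return(rois)
  }

  if (geom != "box") stopf("whole_box_resize requires a box annotation")
  x0 <- ann$x0; y0 <- ann$y0; x1 <- ann$x1; y1 <- ann$y1
  ri <- max(1L, floor(y0) + 1L); ci <- max(1L, floor(x0) + 1L)
  re <- min(H, ceiling(y1)); ce <- min(W, ceiling(x1))
  if (re <= ri || ce <= ci) stopf("box annotation lies outside the image")
  crop <- image[ri:re, ci:ce, drop = FALSE]
  px <- clip01(EBImage::resize(crop, w = side, h = side,
                               antialias = side < min(dim(crop))))
  list(gray_roi(matrix(px, side, side), label, id, offset = c(ri, ci)))
}

# 90-degree counter-clockwise rotation as an exact pixel permutation.
rot90_once <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

apply_transform <- function(m, rotation, flip) {
  k <- (rotation %/% 90L) %% 4L
  for (i in seq_len(k)) m <- rot90_once(m)
  if (flip == "ud") m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (flip == "lr") m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  m
}

#' Augment ROIs by exact rotations and optional flips
#'
#' Rotations are restricted to multiples of 90 degrees so every transform is a
#' pixel permutation (no interpolation). With `flips = TRUE` each rotation is
#' additionally emitted with an up-down and a left-right flip (3 variants per
#' rotation); the default is rotations only, so four rotations quadruple the
#' sample count (e.g. 144 ROIs become 576 samples).
#'
#' @param rois A [gray_roi] or list of them.
#' @param rotations Angles in degrees, multiples of 90 (default
#'   `c(0, 90, 180, 270)`).
#' @param flips Logical; add up-down and left-right flipped variants.
#' @return List of [gray_roi] objects, each tagged with its transform.
#' @export
augment_rois <- function(rois, rotations = c(0, 90, 180, 270), flips = FALSE) {
  if (inherits(rois, "gray_roi")) rois <- list(rois)
  if (any(rotations %% 90 != 0)) stopf("rotations must be multiples of 90 degrees")
  flip_set <- if (isTRUE(flips)) c("none", "ud", "lr") else "none"
  out <- vector("list", length(rois) * length(rotations) * length(flip_set))
  i <- 0L
  for (roi in rois) {
    for (rot in rotations) {
      for (fl in flip_set) {
        px <- apply_transform(roi$pixels, as.integer(rot), fl)
        tag <- sprintf("rot%d%s", as.integer(rot) %% 360L,
                       if (fl == "none") "" else paste0("+", fl))
        i <- i + 1L
        out[[i]] <- gray_roi(px, roi$label, roi$source$image_id,
                             offset = roi$source$offset, transform = tag)
      }
    }
  }
  out
}
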