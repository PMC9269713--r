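#' Contrast-limited adaptive histogram equalization (CLAHE) channel
#'
#' Local histogram equalization over a tile grid with a clip limit bounding
#' noise amplification. The clip limit is given as a fraction of the tile's
#' pixel count per histogram bin (so `0.01` caps every bin at 1% of the tile
#' mass), the convention most image-processing toolkits use.
#'
#' @param roi A [gray_roi] or a numeric matrix in `[0, 1]`.
#' @param clip_limit Normalized clip limit, `> 0` (default 0.01).
#' @param tiles Integer `(rows, cols)` of the contextual-region grid
#'   (default `c(8, 8)`).
#' @param bins Histogram bins (default 256, matching 8-bit sources).
#' @return Numeric matrix, same shape as the input, values in `[0, 1]`.
#' @export
clahe_channel <- function(roi, clip_limit = 0.01, tiles = c(8, 8), bins = 256) {
  px <- if (inherits(roi, "gray_roi")) roi$pixels else roi
  check_intensity(px)
  if (clip_limit <= 0) stopf("clip_limit must be positive")
  tiles <- as.integer(rep(tiles, length.out = 2L))
  if (any(tiles < 1L)) stopf("tiles must be at least (1,1)")
  if (tiles[[1]] > nrow(px) || tiles[[2]] > ncol(px))
    stopf("tile grid %dx%d larger than image %dx%d", tiles[[1]], tiles[[2]], nrow(px), ncol(px))
  # EBImage's first array dimension is horizontal; our matrices are row = y.
  out <- EBImage::clahe(t(px), nx = tiles[[2]], ny = tiles[[1]], bins = bins,
                        limit = clip_limit * bins)
  clip01(t(as.matrix(out)))
}

#' Percentile intensity stretch
#'
#' Linearly rescales intensities so that values at or below the `low`-th
#' percentile saturate to 0 and values at or above the `(100 - high)`-th
#' percentile saturate to 1. Percentiles are computed per image by linear
#' interpolation between order statistics. If the two percentile values
#' coincide (e.g. a constant image) the input is returned unchanged.
#'
#' @param roi A [gray_roi] or numeric matrix in `[0, 1]`.
#' @param low,high Percent of pixel mass saturated at each end (default 1
#'   and 1); `low + high` must be below 100.
#' @return Numeric matrix, same shape, values in `[0, 1]`.
#' @export
percentile_stretch <- function(roi, low = 1, high = 1) {
  px <- if (inherits(roi, "gray_roi")) roi$pixels else roi
  check_intensity(px)
  if (low < 0 || high < 0 || low + high >= 100) stopf("need low, high >= 0 and low + high < 100")
  q <- stats::quantile(px, c(low, 100 - high) / 100, names = FALSE, type = 7)
  if (q[[2]] <= q[[1]]) return(px)
  clip01((px - q[[1]]) / (q[[2]] - q[[1]]))
}

#' Build a three-channel pseudo-color image from one grayscale ROI
#'
#' Channel 1 (red) is the untouched source patch, channel 2 (green) its CLAHE
#' equalization, channel 3 (blue) its percentile-stretched version. Stacking
#' three deterministic views of the same patch gives color-input backbones
#' richer information than replicating the grayscale plane.
#'
#' @param roi A [gray_roi] or numeric matrix in `[0, 1]`.
#' @param clip_limit,tiles CLAHE parameters, see [clahe_channel()].
#' @param low,high Stretch percentiles, see [percentile_stretch()].
#' @return An H x W x 3 array of class `pseudo_color` with attribute
#'   `channel_roles = c("original", "clahe", "stretched")`.
#' @export
to_pseudo_color <- function(roi, clip_limit = 0.01, tiles = c(8, 8), low = 1, high = 1) {
  px <- if (inherits(roi, "gray_roi")) roi$pixels else roi
  check_intensity(px)
  arr <- array(0, dim = c(nrow(px), ncol(px), 3L))
  arr[, , 1L] <- px
  arr[, , 2L] <- clahe_channel(px, clip_limit = clip_limit, tiles = tiles)
  arr[, , 3L] <- percentile_stretch(px, low = low, high = high)
  structure(arr, channel_roles = c("original", "clahe", "stretched"),
            class = c("pseudo_color", "array"))
}

#' Resize a pseudo-color image to a backbone's input size
#'
#' Bilinear interpolation with an anti-aliasing filter, the standard
#' preparation for feeding small patches to a fixed-input CNN (227 for
#' AlexNet, 224 for VGG16/GoogLeNet).
#'
#' @param img A `pseudo_color` array (H x W x 3) or grayscale matrix.
#' @param target Target side in pixels.
#' @return `target` x `target` x 3 `pseudo_color` array, values in `[0, 1]`.
#' @export
resize_for_backbone <- function(img, target) {
  target <- as.integer(target)
  if (is.na(target) || target < 1L) stopf("target side must be positive")
  if (is.matrix(img)) img <- to_pseudo_color_stackgray(img)
  if (length(dim(img)) != 3L || dim(img)[[3]] != 3L) stopf("expected an H x W x 3 image")
  if (all(dim(img)[1:2] == target)) return(img)
  out <- array(0, dim = c(target, target, 3L))
  aa <- target < min(dim(img)[1:2])   # anti-alias filter only when decimating
  for (c in 1:3) {
    out[, , c] <- clip01(t(as.matrix(
      EBImage::resize(t(img[, , c]), w = target, h = target, antialias = aa))))
  }
  structure(out, channel_roles = attr(img, "channel_roles"),
            class = c("pseudo_color", "array"))
}

# Grayscale fed where three channels are expected: replicate the plane
# (the conventional grayscale baseline the pseudo-color mapping improves on).
to_pseudo_color_stackgray <- function(px) {
  structure(array(rep(px, 3L), dim = c(nrow(px), ncol(px), 3L)),
            channel_roles = rep("original", 3L),
            class = c("pseudo_color", "array"))
}
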