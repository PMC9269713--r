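circle_ann <- function(cx, cy, r, origin = "top_left", class = "benign") {
  data.frame(image_id = "img1", lesion_class = class, geometry = "circle",
             cx = cx, cy = cy, radius = r, x0 = NA, y0 = NA, x1 = NA, y1 = NA,
             origin = origin, stringsAsFactors = FALSE)
}

test_that("tile extraction returns pairwise-disjoint in-circle tiles", {
  img <- matrix(runif(600 * 600), 600, 600)
  ann <- circle_ann(300, 300, 197)
  rois <- extract_rois(img, ann, side = 32)
  expect_gt(length(rois), 0L)
  offs <- lapply(rois, function(r) r$source$offset)
  for (i in seq_along(offs)) {
    for (j in seq_len(i - 1L)) {
      expect_false(squares_overlap(offs[[i]], offs[[j]], 32))
    }
    # all four tile corners inside the circle (0-based centers)
    ri <- offs[[i]][[1]] - 1; ci <- offs[[i]][[2]] - 1
    corners <- expand.grid(y = c(ri, ri + 31), x = c(ci, ci + 31))
    expect_true(all((corners$x - 300)^2 + (corners$y - 300)^2 <= 197^2))
    # pixels are a faithful crop
    expect_identical(rois[[i]]$pixels,
                     img[offs[[i]][[1]] + 0:31, offs[[i]][[2]] + 0:31])
  }
})

test_that("lesions smaller than one tile give an empty extraction", {
  img <- matrix(0.5, 100, 100)
  expect_length(extract_rois(img, circle_ann(50, 50, 10), side = 32), 0L)
})

test_that("tiles exceeding image bounds are dropped, not padded", {
  img <- matrix(0.5, 120, 120)
  # circle centered near the corner: some candidate tiles fall off-image
  rois <- suppressMessages(extract_rois(img, circle_ann(30, 30, 60), side = 32))
  for (r in rois) {
    expect_true(all(r$source$offset >= 1))
    expect_true(all(r$source$offset + 31 <= 120))
  }
})

test_that("bottom-left annotation origins are flipped to raster coordinates", {
  img <- matrix(0, 200, 200)
  img[11:70, 71:130] <- 1          # bright block around raster row 40, col 100
  # annotation stores the center in bottom-left coordinates: y = 199 - 40
  ann <- circle_ann(100, 199 - 40, 60, origin = "bottom_left")
  rois <- suppressMessages(extract_rois(img, ann, side = 32))
  expect_gt(length(rois), 0L)
  expect_gt(mean(rois[[1]]$pixels), 0.5)
})

test_that("whole-box extraction resizes the crop to one square ROI", {
  img <- matrix(runif(100 * 100), 100, 100)
  ann <- data.frame(image_id = "b", lesion_class = "malignant", geometry = "box",
                    cx = NA, cy = NA, radius = NA, x0 = 0, y0 = 0, x1 = 64, y1 = 64,
                    origin = "top_left", stringsAsFactors = FALSE)
  rois <- extract_rois(img, ann, mode = "whole_box_resize", side = 32)
  expect_length(rois, 1L)
  expect_equal(dim(rois[[1]]$pixels), c(32L, 32L))
  expect_true(all(rois[[1]]$pixels >= 0 & rois[[1]]$pixels <= 1))
})

test_that("rotation augmentation multiplies counts exactly and losslessly", {
  rois <- lapply(1:3, function(i) gray_roi(matrix(runif(16), 4, 4), "benign", "im"))
  aug <- augment_rois(rois)
  expect_length(aug, 12L)                      # 4 rotations x 3 ROIs
  aug_f <- augment_rois(rois[[1]], flips = TRUE)
  expect_length(aug_f, 12L)                    # 4 rotations x 3 flip variants
  # every transform preserves the pixel multiset
  for (a in aug_f) expect_equal(sort(a$pixels), sort(rois[[1]]$pixels))
  expect_error(augment_rois(rois, rotations = c(0, 45)), "multiples of 90")
})

test_that("rotations are exact permutations with the expected symmetries", {
  px <- matrix(runif(25), 5, 5)
  roi <- gray_roi(px, "malignant", "im")
  expect_identical(augment_rois(roi, rotations = 0)[[1]]$pixels, px)
  r90 <- augment_rois(roi, rotations = 90)[[1]]
  back <- r90
  for (i in 1:3) back <- augment_rois(back, rotations = 90)[[1]]
  expect_identical(back$pixels, px)
  r180 <- augment_rois(roi, rotations = 180)[[1]]$pixels
  expect_identical(r180, px[5:1, 5:1])
})
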