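test_that("CLAHE maps constants to constants and boosts low contrast", {
  const <- matrix(0.5, 32, 32)
  out <- clahe_channel(const)
  expect_lt(diff(range(out)), 1e-12)

  blob <- blob_roi()
  enhanced <- clahe_channel(blob)
  expect_equal(dim(enhanced), dim(blob))
  expect_true(all(enhanced >= 0 & enhanced <= 1))
  expect_gte(sd(enhanced), sd(blob))
})

test_that("CLAHE widens a mid-gray checkerboard toward the full range", {
  chk <- checker_image()
  out <- clahe_channel(chk)
  expect_gt(diff(range(out)), diff(range(chk)))
})

test_that("CLAHE validates its tile grid", {
  expect_error(clahe_channel(matrix(0.5, 8, 8), tiles = c(16, 16)), "larger than image")
  expect_error(clahe_channel(blob_roi(), clip_limit = 0), "positive")
})

test_that("percentile stretch saturates the expected pixel mass on a ramp", {
  rmp <- ramp_image(100)
  out <- percentile_stretch(rmp, low = 1, high = 1)
  expect_true(all(out >= 0 & out <= 1))
  frac0 <- mean(out == 0); frac1 <- mean(out == 1)
  expect_gt(frac0, 0.005); expect_lt(frac0, 0.02)
  expect_gt(frac1, 0.005); expect_lt(frac1, 0.02)
  # monotone non-decreasing intensity mapping
  expect_true(all(diff(out[order(rmp)]) >= -1e-12))
})

test_that("percentile stretch is identity on constants and idempotent at the bounds", {
  const <- matrix(0.3, 10, 10)
  expect_identical(percentile_stretch(const), const)
  # after a 2%/2% stretch the 1%/99% percentile values are exactly 0 and 1,
  # so a further 1%/1% stretch is the identity
  once <- percentile_stretch(ramp_image(50), low = 2, high = 2)
  twice <- percentile_stretch(once, low = 1, high = 1)
  expect_equal(twice, once, tolerance = 1e-12)
  expect_error(percentile_stretch(ramp_image(10), low = 60, high = 50), "low \\+ high")
})

test_that("pseudo-color stacks keep the source untouched in channel 1", {
  blob <- blob_roi()
  pc <- to_pseudo_color(blob)
  expect_equal(dim(pc), c(32L, 32L, 3L))
  expect_identical(pc[, , 1], blob)           # bit-identical source channel
  expect_false(identical(pc[, , 1], pc[, , 2]))
  expect_false(identical(pc[, , 1], pc[, , 3]))
  expect_false(identical(pc[, , 2], pc[, , 3]))
  expect_equal(attr(pc, "channel_roles"), c("original", "clahe", "stretched"))

  const <- matrix(0.5, 32, 32)
  pcc <- to_pseudo_color(const)
  for (k in 1:3) expect_lt(diff(range(pcc[, , k])), 1e-12)
})

test_that("backbone resizing hits the target size and preserves range", {
  pc <- to_pseudo_color(blob_roi())
  big <- resize_for_backbone(pc, 227)
  expect_equal(dim(big), c(227L, 227L, 3L))
  expect_true(all(big >= 0 & big <= 1))

  same <- resize_for_backbone(big, 227)
  expect_identical(same, big)                 # identity resize

  const <- mammocad:::to_pseudo_color_stackgray(matrix(0.4, 32, 32))
  cbig <- resize_for_backbone(const, 64)
  expect_lt(diff(range(cbig)), 1e-9)

  expect_error(resize_for_backbone(pc, 0), "positive")
})
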