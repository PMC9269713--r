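test_that("the backbone registry reports the published contract", {
  reg <- backbone_registry()
  expect_setequal(reg$name, c("alexnet", "googlenet", "vgg16", "fallback"))
  expect_equal(backbone_registry("alexnet")$feature_dim, 4096L)
  expect_equal(backbone_registry("alexnet")$input_side, 227L)
  expect_equal(backbone_registry("googlenet")$feature_dim, 1024L)
  expect_equal(backbone_registry("googlenet")$input_side, 224L)
  expect_equal(backbone_registry("vgg16")$feature_dim, 4096L)
  expect_equal(backbone_registry("vgg16")$input_side, 224L)
  expect_error(backbone_registry("resnet50"), "unknown backbone")
})

test_that("architecture tables yield the published parameter counts", {
  expect_equal(count_parameters("alexnet"), 61)
  expect_equal(count_parameters("vgg16"), 138)
  expect_equal(count_parameters("googlenet"), 7)
  expect_error(count_parameters("fallback"), "no fixed architecture")
})

test_that("fallback extraction is deterministic with orthonormal projection", {
  imgs <- lapply(1:10, function(i) blob_roi(32, contrast = i / 20))
  f1 <- fallback_extract(imgs, dim = 50, seed = 0)
  f2 <- fallback_extract(imgs, dim = 50, seed = 0)
  expect_equal(dim(f1), c(10L, 50L))
  expect_identical(f1, f2)

  proj <- mammocad:::fallback_projection(dim = 50, seed = 0)
  gram <- crossprod(proj)
  expect_lt(max(abs(gram - diag(50))), 1e-8)

  # distinct constant images map to distinct rows
  fc <- fallback_extract(list(matrix(0.2, 32, 32), matrix(0.8, 32, 32)), dim = 20)
  expect_gt(max(abs(fc[1, ] - fc[2, ])), 1e-6)

  expect_error(fallback_extract(imgs, dim = 0), "at least 1")
  expect_error(fallback_extract(imgs, dim = 10000), "at most")
})

test_that("deep backbones honour the feature-dimension shape contract", {
  pc <- to_pseudo_color(blob_roi())
  img224 <- resize_for_backbone(pc, 224)
  img227 <- resize_for_backbone(pc, 227)

  fg <- extract_features(list(a = img224, b = img224), "googlenet", seed = 3)
  expect_equal(dim(fg), c(2L, 1024L))
  expect_identical(fg[1, ], fg[2, ])          # determinism on repeated input

  fa <- extract_features(list(x = img227), "alexnet", seed = 3)
  expect_equal(dim(fa), c(1L, 4096L))

  fv <- extract_features(list(x = img224), "vgg16", seed = 3)
  expect_equal(dim(fv), c(1L, 4096L))

  empty <- extract_features(list(), "alexnet", seed = 1)
  expect_equal(dim(empty), c(0L, 4096L))

  expect_error(extract_features(list(img224), "alexnet", seed = 1), "227")
  expect_error(extract_features(list(img227), "alexnet",
                                weights_source = "pretrained"),
               "random_seeded")
})

test_that("feature matrices round-trip through delimited text", {
  imgs <- lapply(1:4, function(i) blob_roi(32, contrast = i / 10))
  names(imgs) <- paste0("s", 1:4)
  f <- fallback_extract(imgs, dim = 12, seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_features(f, path)
  g <- read_features(path)
  expect_equal(unname(g), unname(f), tolerance = 1e-12)
  expect_equal(rownames(g), rownames(f))
  expect_equal(attr(g, "backbone"), "fallback")
  expect_true(file.exists(paste0(path, ".json")))
})
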