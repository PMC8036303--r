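test_that("GLCM of degenerate and structured images", {
  # constant image: all co-occurrence mass in one cell
  g <- glcm(matrix(5, 8, 8), levels = 4)
  expect_equal(max(g$matrix), 1)
  expect_equal(sum(g$matrix), 1)

  # checkerboard at offset (0,1): only (0,1) and (1,0) transitions
  g2 <- glcm(checkerboard(8), levels = 2, offset = c(0, 1))
  expect_equal(g2$matrix[1, 2], 0.5)
  expect_equal(g2$matrix[2, 1], 0.5)
  expect_equal(g2$matrix[1, 1] + g2$matrix[2, 2], 0)

  # any GLCM is a probability distribution
  set.seed(41)
  g3 <- glcm(matrix(runif(64), 8, 8), levels = 8, offset = c(1, -1))
  expect_equal(sum(g3$matrix), 1, tolerance = 1e-9)
  expect_true(all(g3$matrix >= 0))

  expect_error(glcm(matrix(1:2, 1, 2), levels = 2, offset = c(1, 0)), "smaller")
})

test_that("Haralick statistics take their hand-computed values", {
  feats_const <- haralick_features(glcm(matrix(3, 8, 8), levels = 4))
  expect_equal(feats_const[["energy"]], 1)
  expect_equal(feats_const[["entropy"]], 0)
  expect_equal(feats_const[["contrast"]], 0)

  feats_cb <- haralick_features(glcm(checkerboard(8), levels = 2, offset = c(0, 1)))
  expect_equal(feats_cb[["contrast"]], 1)
  expect_equal(feats_cb[["energy"]], 0.5)

  # uniform co-occurrence: entropy = 2 log2(G) bits
  G <- 4
  feats_u <- haralick_features(matrix(1 / G^2, G, G))
  expect_equal(feats_u[["entropy"]], 2 * log2(G))
})

test_that("Haralick features are invariant to adding a constant to the image", {
  set.seed(42)
  img <- matrix(runif(256), 16, 16)
  f1 <- haralick_features(glcm(img, levels = 8))
  f2 <- haralick_features(glcm(img + 3.7, levels = 8))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("patch-wise bag extraction tiles the image deterministically", {
  set.seed(43)
  img <- matrix(runif(64 * 64), 64, 64)
  bag <- image_to_bag(img, image_id = "t", patch_size = 16, stride = 16)
  expect_equal(nrow(bag$vectors), 16L)
  expect_equal(ncol(bag$vectors), 13L)
  expect_true(all(bag$vectors > 0))
  expect_equal(rowSums(bag$vectors), rep(1, 16), tolerance = 1e-9)

  bag2 <- image_to_bag(img, image_id = "t", patch_size = 16, stride = 16)
  expect_identical(bag$vectors, bag2$vectors)

  expect_error(image_to_bag(matrix(0.5, 8, 8), patch_size = 16), "smaller")
})

test_that("synthetic texture classes are generated reproducibly and differ in contrast", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  info1 <- make_texture_images(d1, n_per_class = 3, size = 64, seed = 9)
  info2 <- make_texture_images(d2, n_per_class = 3, size = 64, seed = 9)
  expect_equal(nrow(info1), 6L)
  expect_identical(readBin(info1$path[1], "raw", 1e5),
                   readBin(info2$path[1], "raw", 1e5))
  img <- read_gray_image(info1$path[1])
  expect_equal(dim(img), c(64L, 64L))

  contrast_of <- function(p) {
    mean(vapply(seq_len(nrow(p)), function(i) {
      haralick_features(glcm(read_gray_image(p$path[i]), levels = 8))[["contrast"]]
    }, numeric(1)))
  }
  smooth <- info1[info1$class == "smooth", ]
  speckle <- info1[info1$class == "speckle", ]
  expect_gt(contrast_of(speckle), contrast_of(smooth))
})

test_that("feature bags survive a round trip through the TSV format", {
  mk <- test_mixture_k2()
  bags <- lapply(1:3, function(i) {
    feature_bag(paste0("img", i), rssd_mixture(10, mk, seed = 70 + i))
  })
  names(bags) <- paste0("img", 1:3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_bags(bags, f)
  back <- read_bags(f)
  expect_equal(names(back), names(bags))
  expect_equal(back[["img2"]]$vectors, bags[["img2"]]$vectors,
               tolerance = 1e-12, ignore_attr = TRUE)

  lf <- withr::local_tempfile(fileext = ".tsv")
  labels <- c(img1 = "a", img2 = "b", img3 = "a")
  write_labels(labels, lf)
  expect_equal(read_labels(lf), labels)
})

test_that("mixture models survive a round trip through JSON", {
  mk <- test_mixture_k2()
  f <- withr::local_tempfile(fileext = ".json")
  write_ssd_model(mk, f)
  back <- read_ssd_model(f)
  expect_equal(back$weights, mk$weights)
  expect_equal(back$components[[2]]$alpha, mk$components[[2]]$alpha)
  expect_equal(back$components[[2]]$beta, mk$components[[2]]$beta)
  expect_equal(back$components[[2]]$b, mk$components[[2]]$b)
})
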