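test_that("loading records native geometry and binarizes masks", {
  root <- withr::local_tempdir()
  # DRIVE-shaped: 584 rows x 565 cols
  img <- withr::with_seed(1, array(runif(584 * 565 * 3), c(584, 565, 3)))
  vessel <- matrix(0, 584, 565); vessel[100:120, 200:360] <- 1
  fov <- matrix(1, 584, 565)
  png::writePNG(img, file.path(root, "img.png"))
  png::writePNG(vessel * 0.8 + 0.1, file.path(root, "vessel.png"))  # anti-aliased-ish levels
  png::writePNG(fov, file.path(root, "fov.png"))
  s <- loadSample(file.path(root, "img.png"), file.path(root, "vessel.png"),
                  file.path(root, "fov.png"))
  expect_equal(nativeDim(s), c(584L, 565L))
  expect_true(all(sampleImage(s) >= 0 & sampleImage(s) <= 1))
  expect_setequal(unique(as.numeric(vesselMask(s))), c(0, 1))
  expect_equal(vesselMask(s), vessel)
  # size mismatch names the offending file
  png::writePNG(matrix(1, 10, 10), file.path(root, "bad.png"))
  expect_error(loadSample(file.path(root, "img.png"),
                          file.path(root, "bad.png"),
                          file.path(root, "fov.png")), "bad\\.png")
})

test_that("min-max normalization maps ranges onto [0, 1]", {
  x <- matrix(c(0, 128, 255), 1)
  expect_equal(range(normalizeImage(x)), c(0, 1))
  expect_equal(normalizeImage(matrix(5, 3, 3)), matrix(0, 3, 3))
  y <- matrix(c(0, 0.4, 1), 1)
  expect_equal(normalizeImage(y), y)
})

test_that("histogram equalization follows the empirical CDF", {
  expect_equal(equalizeImage(matrix(0.3, 8, 8)), matrix(0.3, 8, 8))
  # 50% at 0.2, 50% at 0.8 -> CDF map pushes levels to 0.5 and 1.0
  x <- matrix(c(rep(0.2, 32), rep(0.8, 32)), 8, 8)
  y <- equalizeImage(x)
  expect_equal(sort(unique(as.numeric(y))), c(0.5, 1.0))
  expect_true(all((x[1, ] < x[2, ]) == (y[1, ] < y[2, ])))  # order preserved
  # Kolmogorov distance to uniform does not increase
  z <- withr::with_seed(2, matrix(rbeta(64 * 64, 5, 2), 64, 64))
  ks <- function(v) {
    v <- sort(v)
    max(abs(seq_along(v) / length(v) - v))
  }
  expect_lte(ks(as.numeric(equalizeImage(z))), ks(as.numeric(z)))
})

test_that("pad and crop are exact inverses with the documented offsets", {
  # DRIVE-shaped sample
  s <- withr::with_seed(3, {
    img <- array(runif(584 * 565 * 3), c(584, 565, 3))
    vm <- matrix(rbinom(584 * 565, 1, 0.1), 584, 565)
    FundusSample(img, vm, matrix(1, 584, 565), sampleId = "drive")
  })
  p <- padTo(s, 592L, 592L)
  expect_equal(p$record$offsetRow, 4L)
  expect_equal(p$record$offsetCol, 13L)
  expect_equal(dim(sampleImage(p$sample)), c(592L, 592L, 3L))
  expect_identical(cropBack(sampleImage(p$sample), p$record), sampleImage(s))
  expect_identical(cropBack(vesselMask(p$sample), p$record), vesselMask(s))
  expect_equal(dim(cropBack(vesselMask(p$sample), p$record)), c(584L, 565L))
  # CHASE-shaped target is accepted
  s2 <- FundusSample(array(0.5, c(960, 999, 3)), matrix(0, 960, 999),
                     matrix(1, 960, 999), sampleId = "chase")
  p2 <- padTo(s2, 1008L, 1008L)
  expect_equal(dim(sampleImage(p2$sample))[1:2], c(1008L, 1008L))
  # all-ones map survives the round trip untouched
  ones <- matrix(1, 592, 592)
  expect_true(all(cropBack(ones, p$record) == 1))
  # down-scaling is out of contract
  expect_error(padTo(s, 500L, 592L), "smaller")
  expect_error(cropBack(matrix(0, 10, 10), p$record), "pad record")
})

test_that("bilinear resize preserves constants and average intensity", {
  x <- matrix(0.4, 20, 20)
  y <- resizeImage(x, 37, 11)
  expect_equal(dim(y), c(37L, 11L))
  expect_true(all(abs(y - 0.4) < 1e-12))
  z <- withr::with_seed(4, matrix(runif(64^2), 64, 64))
  expect_equal(mean(resizeImage(z, 32, 32)), mean(z), tolerance = 0.01)
})

test_that("train/validation split is a deterministic partition", {
  ids <- sprintf("im%02d", 20:1)
  sp <- splitTrainVal(ids, 0.9)
  expect_length(sp$train, 18L)
  expect_length(sp$val, 2L)
  expect_setequal(c(sp$train, sp$val), ids)
  expect_length(intersect(sp$train, sp$val), 0L)
  sp10 <- splitTrainVal(sprintf("s%02d", 1:10))
  expect_length(sp10$train, 9L)
  expect_length(sp10$val, 1L)
  expect_identical(splitTrainVal(ids, 0.9), sp)
  expect_error(splitTrainVal("one"), "at least 2")
  expect_error(splitTrainVal(c("a", "a", "b")), "unique")
})

test_that("augmentations act on the right planes and stay involutive", {
  s <- tinySample()
  h <- applyAugment(s, list(kind = "hflip", magnitude = 0))
  hh <- applyAugment(h, list(kind = "hflip", magnitude = 0))
  expect_identical(sampleImage(hh), sampleImage(s))
  expect_identical(vesselMask(hh), vesselMask(s))
  v <- applyAugment(s, list(kind = "vflip", magnitude = 0))
  vv <- applyAugment(v, list(kind = "vflip", magnitude = 0))
  expect_identical(vesselMask(vv), vesselMask(s))
  # geometric ops move image and masks together
  expect_identical(vesselMask(h), vesselMask(s)[, ncol(vesselMask(s)):1])
  # zero-magnitude noise changes nothing
  n0 <- withr::with_seed(1, applyAugment(s, list(kind = "gaussian_noise",
                                                 magnitude = 0)))
  expect_identical(sampleImage(n0), sampleImage(s))
  # intensity ops leave the masks untouched and the image in range
  for (k in c("contrast", "gaussian_noise")) {
    a <- withr::with_seed(2, applyAugment(s, list(kind = k, magnitude = if (k == "contrast") 1.2 else 0.03)))
    expect_identical(vesselMask(a), vesselMask(s))
    expect_identical(fovMask(a), fovMask(s))
    expect_true(all(sampleImage(a) >= 0 & sampleImage(a) <= 1))
    expect_true(all(vesselMask(a) %in% c(0, 1)))
  }
})

test_that("the four augmentation kinds are drawn uniformly", {
  kinds <- withr::with_seed(123, {
    replicate(10000, augmentChoice()$kind)
  })
  freq <- table(kinds) / 10000
  expect_setequal(names(freq), c("hflip", "vflip", "contrast",
                                 "gaussian_noise"))
  expect_true(all(abs(freq - 0.25) < 0.02))
  # magnitudes stay within their documented bands
  draws <- withr::with_seed(5, replicate(200, {
    ch <- augmentChoice()
    c(contrast = ch$kind == "contrast" &&
        (ch$magnitude < 0.8 || ch$magnitude > 1.2),
      noise = ch$kind == "gaussian_noise" &&
        (ch$magnitude < 0.005 || ch$magnitude > 0.03))
  }))
  expect_false(any(draws))
})

test_that("loading is idempotent across a write/load cycle", {
  root1 <- withr::local_tempdir()
  root2 <- withr::local_tempdir()
  s <- simulateDataset(1, simConfig(seed = 6L))
  writeDataset(s, root1, force = TRUE)
  l1 <- loadDataset(root1)
  writeDataset(l1, root2, force = TRUE)
  l2 <- loadDataset(root2)
  expect_identical(sampleImage(l2[[1]]), sampleImage(l1[[1]]))
  expect_identical(vesselMask(l2[[1]]), vesselMask(l1[[1]]))
})
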