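# Image I/O, grayscale conversion, augmentation, and partitioning.

test_that("image files round-trip and degenerate inputs are handled", {
  img <- randomTestImage(1, 20, 24)
  dir <- withr::local_tempdir()
  png <- file.path(dir, "a.png")
  saveImage(img, png)
  expect_identical(loadImage(png)@.Data, img@.Data)
  # single-channel TIFF comes back replicated across the three channels
  gray <- file.path(dir, "g.tif")
  EBImage::writeImage(EBImage::Image(matrix(runif(64), 8, 8)), gray)
  gi <- loadImage(gray)
  expect_identical(dim(gi@.Data), c(8L, 8L, 3L))
  expect_identical(gi@.Data[, , 1], gi@.Data[, , 2])
  expect_error(loadImage(file.path(dir, "missing.png")), "not found")
  bad <- file.path(dir, "trunc.png")
  writeBin(readBin(png, "raw", 60), bad)
  expect_error(loadImage(bad), "decode")
})

test_that("grayscale conversion uses the declared luminance weights", {
  red <- RGBImage(array(rep(c(255, 0, 0), each = 4), dim = c(2, 2, 3)))
  expect_true(all(toGrayscale(red) == 76))   # round(0.299 * 255) = 76
  white <- RGBImage(array(255, dim = c(2, 2, 3)))
  expect_true(all(toGrayscale(white) == 255))
  for (v in c(0, 17, 128, 254)) {
    g <- RGBImage(array(v, dim = c(3, 3, 3)))
    expect_true(all(toGrayscale(g) == v))    # idempotent on gray input
  }
})

test_that("zero-strength augmentation is the identity; forced flips are involutions", {
  img <- randomTestImage(2, 24, 24)
  zero <- augmentSpec(hflipProb = 0, vflipProb = 0, maxRotation = 0,
                      brightnessDelta = 0, contrastDelta = 0,
                      saturationDelta = 0, seed = 5)
  expect_identical(augmentImage(img, zero)@.Data, img@.Data)
  hflip <- augmentSpec(hflipProb = 1, vflipProb = 0, maxRotation = 0,
                       brightnessDelta = 0, contrastDelta = 0,
                       saturationDelta = 0, seed = 5)
  once <- augmentImage(img, hflip)
  expect_false(identical(once@.Data, img@.Data))
  expect_identical(augmentImage(once, hflip)@.Data, img@.Data)
  # determinism for a fixed seed
  full <- augmentSpec(seed = 11)
  expect_identical(augmentImage(img, full)@.Data,
                   augmentImage(img, full)@.Data)
})

test_that("sampled rotation angles cover but never exceed the +/-15 degree range", {
  img <- RGBImage(array(128, dim = c(32, 32, 3)))
  spec0 <- augmentSpec(hflipProb = 0, vflipProb = 0, maxRotation = 15,
                       brightnessDelta = 0, contrastDelta = 0,
                       saturationDelta = 0)
  angles <- vapply(1:1000, function(s) {
    sp <- augmentSpec(hflipProb = 0, vflipProb = 0, maxRotation = 15,
                      brightnessDelta = 0, contrastDelta = 0,
                      saturationDelta = 0, seed = s)
    augmentImage(img, sp, returnParams = TRUE)$params$angle
  }, numeric(1))
  expect_gte(min(angles), -15)
  expect_lte(max(angles), 15)
  expect_lte(min(angles), -14)
  expect_gte(max(angles), 14)
})

test_that("the 70/15/15 partition hits the rounded targets and covers the data", {
  mk <- function(n, labels) {
    img <- RGBImage(array(0, dim = c(32, 32, 3)))
    HistoDataset(rep(list(img), n), labels)
  }
  ds <- mk(1000, rep(c(1L, 2L), 500))
  sp <- partitionDataset(ds, splitSpec(seed = 3))
  expect_identical(unname(vapply(sp, length, integer(1))),
                   c(700L, 150L, 150L))
  ds10 <- mk(10, rep(c(1L, 2L), 5))
  sp10 <- partitionDataset(ds10, splitSpec(stratify = FALSE, seed = 3))
  # floor-then-largest-remainder with ties broken train, val, test
  expect_identical(unname(vapply(sp10, length, integer(1))), c(7L, 2L, 1L))
  expect_error(partitionDataset(ds10, splitSpec(c(0.5, 0.2, 0.2))), "sum")
})

test_that("stratified splits preserve per-class shares within one item", {
  img <- RGBImage(array(0, dim = c(32, 32, 3)))
  ds <- HistoDataset(rep(list(img), 100), rep(c(1L, 2L), c(60, 40)))
  sp <- partitionDataset(ds, splitSpec(stratify = TRUE, seed = 8))
  for (part in sp) {
    n1 <- sum(imageLabels(part) == 1L)
    expect_lte(abs(n1 - 0.6 * length(part)), 1)
  }
})

test_that("partitioning is a set partition for every seed", {
  img <- RGBImage(array(0, dim = c(32, 32, 3)))
  labels <- rep(c(1L, 2L), c(13, 18))
  tags <- sprintf("item%02d", seq_along(labels))
  ds <- HistoDataset(rep(list(img), length(labels)), labels, tags)
  for (seed in c(1L, 7L, 23L, 101L)) {
    sp <- partitionDataset(ds, splitSpec(seed = seed))
    got <- sort(unlist(lapply(sp, imageTags), use.names = FALSE))
    expect_identical(got, sort(tags))
  }
})
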