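# The three handcrafted extractors and their 818-dim fusion.

test_that("all histogram-type features are normalized and correctly sized", {
  for (seed in 1:3) {
    img <- randomTestImage(seed, 24, 24)
    f <- fchFeatures(img)
    expect_length(f, 768L)
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-9)
    l <- lbpFeatures(img)
    expect_length(l, 26L)
    expect_true(all(l >= 0))
    expect_equal(sum(l), 1, tolerance = 1e-9)
    g <- glcmFeatures(img)
    expect_length(g, 24L)
    # energy and homogeneity slots are in [0, 1]; entropies non-negative
    idx <- function(k) k + 6 * (0:3)
    expect_true(all(g[idx(3)] >= 0 & g[idx(3)] <= 1))   # homogeneity
    expect_true(all(g[idx(4)] >= 0 & g[idx(4)] <= 1))   # energy
    expect_true(all(g[idx(6)] >= 0))                    # entropy
  }
})

test_that("a uniform color at a fuzzy bin center puts all mass in one bin", {
  # RGB (252, 189, 0): hue exactly 45 deg (a hue bin center), saturation 1
  # and value 252/255 both beyond the outermost bin centers
  img <- RGBImage(array(rep(c(252, 189, 0), each = 16), dim = c(4, 4, 3)))
  f <- fchFeatures(img)
  expect_identical(which(f > 0), c(fch_127 = 128L))
  expect_equal(unname(f[128]), 1)
})

test_that("fuzzy histograms move less than crisp ones under a small brightness shift", {
  img <- generateImage(histoPreset("easy")$class1, c(48, 48), seed = 21)
  shifted <- RGBImage(pmin(img@.Data + 3, 255))
  fuzzyL1 <- sum(abs(fchFeatures(img) - fchFeatures(shifted)))
  crisp <- histofuse:::.crispColorHistogram
  crispL1 <- sum(abs(crisp(img) - crisp(shifted)))
  expect_lte(fuzzyL1, crispL1)
})

test_that("constant images give the one-hot all-ones LBP pattern", {
  for (v in c(0, 100, 255)) {
    img <- RGBImage(array(v, dim = c(16, 16, 3)))
    l <- lbpFeatures(img)
    # comparator >= makes every neighbor bit 1: uniform pattern, 24 set bits
    expect_identical(which(l > 0), c(lbp_24 = 25L))
    expect_equal(unname(l[25]), 1)
  }
})

test_that("LBP histograms are invariant under 90/180/270 degree rotations", {
  m <- randomTestImage(5, 32, 32)@.Data
  rot90 <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  h0 <- lbpFeatures(RGBImage(m))
  a <- m
  for (k in 1:3) {
    a <- rot90(a)
    expect_equal(unname(lbpFeatures(RGBImage(a))), unname(h0),
                 tolerance = 1e-6)
  }
})

test_that("LBP rejects images smaller than the neighborhood", {
  expect_error(lbpFeatures(RGBImage(array(0, dim = c(6, 20, 3)))),
               "at least 7")
})

test_that("constant images give the degenerate GLCM statistics", {
  img <- RGBImage(array(77, dim = c(12, 12, 3)))
  g <- unname(glcmFeatures(img))
  for (a in 0:3) {
    s <- g[a * 6 + 1:6]
    expect_equal(s, c(0, 0, 1, 1, 0, 0))  # contrast, dissim, homog, energy,
  }                                       # correlation (0-variance), entropy
})

test_that("a two-level checkerboard reproduces hand-computed GLCM values", {
  # quantized levels {0, 63}: gray 0 and 252 (252/4 = 63)
  board <- outer(1:8, 1:8, function(i, j) ifelse((i + j) %% 2 == 0, 252, 0))
  img <- RGBImage(array(rep(board, 3), dim = c(8, 8, 3)))
  g <- glcmFeatures(img)
  expect_equal(unname(g[1]), 63^2)        # contrast at 0 degrees
  expect_equal(unname(g[4]), 0.5)         # energy at 0 degrees
})

test_that("GLCM features agree with the all-pairs loop oracle", {
  for (seed in 1:4) {
    img <- randomTestImage(seed, sample(8:16, 1), sample(8:16, 1))
    expect_equal(unname(glcmFeatures(img)), oracleGLCM(img),
                 tolerance = 1e-9)
  }
})

test_that("the 818-dim handcrafted vector is the exact ordered concatenation", {
  img <- randomTestImage(9, 20, 20)
  h <- handcraftedVector(img)
  expect_length(h, 818L)
  expect_identical(unname(h[1:768]), unname(fchFeatures(img)))
  expect_identical(unname(h[769:794]), unname(lbpFeatures(img)))
  expect_identical(unname(h[795:818]), unname(glcmFeatures(img)))
  expect_identical(handcraftedVector(img), h)   # deterministic
})
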