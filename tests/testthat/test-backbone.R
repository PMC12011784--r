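# The dual-branch cross-attention transformer.

tinyModel <- function(seed = 1L, ...) {
  crossViT(backboneConfig("tiny", ...), seed = seed)
}

test_that("patch embedding produces the expected token counts and errors", {
  mod <- tinyModel()
  img <- randomTestImage(1, 64, 64)
  tok <- embedPatches(img, 8L, mod@params$small)
  expect_identical(dim(tok), c(65L, 32L))      # (64/8)^2 + CLS
  tok16 <- embedPatches(img, 16L, mod@params$large)
  expect_identical(dim(tok16), c(17L, 64L))
  expect_error(embedPatches(img, 12L, mod@params$small), "divisible")
  # zero linear map and zero CLS leave exactly the positional encoding
  p0 <- mod@params$small
  p0$embedW[] <- 0; p0$embedB[] <- 0; p0$cls[] <- 0
  zero <- RGBImage(array(0, dim = c(64, 64, 3)))
  expect_equal(embedPatches(zero, 8L, p0), p0$pos)
})

test_that("an encoder layer with zeroed value/output maps is the identity", {
  mod <- tinyModel()
  p <- mod@params$small$layers[[1]]
  p$Wv[] <- 0; p$bv[] <- 0; p$W2[] <- 0; p$b2[] <- 0
  set.seed(3)
  x <- matrix(rnorm(5 * 32), 5, 32)
  expect_equal(encoderLayer(x, p, heads = 2L), x, tolerance = 1e-12)
})

test_that("encoder layers match the loop-based reference on small inputs", {
  cfg <- backboneConfig("tiny", dimSmall = 8L, dimLarge = 16L, heads = 1L)
  mod <- crossViT(cfg, seed = 4)
  p <- mod@params$small$layers[[1]]
  set.seed(11)
  for (rep in 1:3) {
    x <- matrix(rnorm(3 * 8), 3, 8)
    expect_equal(encoderLayer(x, p, heads = 1L),
                 oracleEncoderLayer(x, p, heads = 1L), tolerance = 1e-6)
  }
  # multi-head agreement too
  p2 <- mod@params$large$layers[[1]]
  x2 <- matrix(rnorm(4 * 16), 4, 16)
  expect_equal(encoderLayer(x2, p2, heads = 2L),
               oracleEncoderLayer(x2, p2, heads = 2L), tolerance = 1e-6)
})

test_that("cross-attention matches the hand-coded evaluation and handles N = 0", {
  cfg <- backboneConfig("tiny", dimSmall = 8L, dimLarge = 12L, heads = 1L)
  mod <- crossViT(cfg, seed = 6)
  p <- mod@params$cross[[1]]$largeFromSmall
  set.seed(21)
  cls <- rnorm(12)
  patches <- matrix(rnorm(2 * 8), 2, 8)
  got <- crossAttentionFuse(cls, patches, p, returnAttention = TRUE)
  expect_equal(got$cls, oracleCrossAttention(cls, patches, p),
               tolerance = 1e-6)
  expect_equal(sum(got$attention), 1, tolerance = 1e-6)
  expect_length(got$attention, 3L)
  # empty patch list: softmax over the single CLS position is 1 and the
  # update reduces to residual + LN(x') W_v (+ bias) of that token
  none <- matrix(0, 0, 8)
  got0 <- crossAttentionFuse(cls, none, p, returnAttention = TRUE)
  expect_equal(got0$attention, 1)
  f <- matrix(cls, 1) %*% p$Wf + rep(p$bf, each = 1)
  m <- mean(f); v <- mean((f - m)^2)
  xn <- (f - m) / sqrt(v + 1e-6) * p$lng + p$lnb
  expect_equal(got0$cls, cls + as.numeric(xn %*% p$Wv + p$bv),
               tolerance = 1e-9)
})

test_that("self-attention rows are probability vectors on random inputs", {
  mod <- tinyModel(seed = 8)
  p <- mod@params$small$layers[[1]]
  set.seed(2)
  Xn <- matrix(rnorm(6 * 32), 6, 32)
  fw <- histofuse:::.fwdMSA(Xn, p, heads = 2L)
  for (A in fw$A) {
    expect_true(all(A >= 0))
    expect_equal(unname(rowSums(A)), rep(1, 6), tolerance = 1e-6)
  }
})

test_that("the full forward pass matches the loop-based reference", {
  cfg <- backboneConfig("tiny", imageSize = 16L, patchSmall = 4L,
                        patchLarge = 8L, dimSmall = 8L, dimLarge = 16L,
                        depth = 2L, heads = 2L, nCrossRounds = 1L)
  mod <- crossViT(cfg, seed = 12)
  img <- randomTestImage(3, 16, 16)
  got <- forwardFeatures(img, mod)
  want <- oracleForwardFeatures(img, mod)
  expect_equal(deepSmall(got), want$small, tolerance = 1e-5)
  expect_equal(deepLarge(got), want$large, tolerance = 1e-5)
  # deterministic in eval mode
  again <- forwardFeatures(img, mod)
  expect_identical(deepSmall(got), deepSmall(again))
})

test_that("branch CLS widths follow the configuration", {
  mod <- tinyModel(seed = 2)
  ft <- forwardFeatures(randomTestImage(4, 64, 64), mod)
  expect_length(deepSmall(ft), 32L)
  expect_length(deepLarge(ft), 64L)
  expect_error(forwardFeatures(randomTestImage(4, 32, 32), mod),
               "does not match")
})

test_that("logit fusion averages the two branch heads", {
  feats <- new("DeepFeatures", small = c(3, 1), large = c(1, 3))
  id <- list(W = diag(2), b = c(0, 0))
  lp <- fuseLogits(feats, headSmall = id, headLarge = id)
  expect_equal(lp$fused, c(2, 2))
  # equal branch outputs pass through unchanged
  same <- new("DeepFeatures", small = c(0.4, -1), large = c(0.4, -1))
  expect_equal(fuseLogits(same, id, id)$fused, c(0.4, -1))
  # random heads against the direct formula
  set.seed(5)
  hS <- list(W = matrix(rnorm(6), 3, 2), b = rnorm(2))
  hL <- list(W = matrix(rnorm(8), 4, 2), b = rnorm(2))
  fts <- new("DeepFeatures", small = rnorm(3), large = rnorm(4))
  want <- 0.5 * (as.numeric(fts@small %*% hS$W) + hS$b +
                   as.numeric(fts@large %*% hL$W) + hL$b)
  expect_equal(fuseLogits(fts, hS, hL)$fused, want, tolerance = 1e-7)
  expect_error(fuseLogits(fts, hL, hS), "head dimensions")
})

test_that("analytic gradients match finite differences", {
  cfg <- backboneConfig("tiny", imageSize = 32L, patchSmall = 8L,
                        patchLarge = 16L, dimSmall = 8L, dimLarge = 12L,
                        depth = 1L, heads = 2L, nCrossRounds = 1L)
  mod <- crossViT(cfg, seed = 3)
  imgs <- list(generateImage(classAppearance(), c(32, 32), 1),
               generateImage(classAppearance(backgroundHue = 200),
                             c(32, 32), 2))
  labs <- c(1L, 2L)
  lossGrad <- histofuse:::.batchLossGrad
  lg <- lossGrad(imgs, labs, mod@params, cfg)
  bump <- function(x, path, i, d) {
    if (length(path) == 0) { x[i] <- x[i] + d; return(x) }
    x[[path[[1]]]] <- bump(x[[path[[1]]]], path[-1], i, d)
    x
  }
  paths <- list(list("headLarge", "W"), list("small", "embedW"),
                list("small", "layers", 1L, "Wq"),
                list("large", "layers", 1L, "W1"),
                list("cross", 1L, "largeFromSmall", "Wf"),
                list("cross", 1L, "smallFromLarge", "Wv"))
  set.seed(42)
  for (path in paths) {
    g <- lg$grads
    for (p in path) g <- g[[p]]
    i <- sample(length(g), 1)
    eps <- 1e-5
    lp <- lossGrad(imgs, labs, bump(mod@params, path, i, +eps), cfg,
                   wantGrad = FALSE)$loss
    lm <- lossGrad(imgs, labs, bump(mod@params, path, i, -eps), cfg,
                   wantGrad = FALSE)$loss
    num <- (lp - lm) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-3)
  }
})

test_that("200 optimizer steps cut the one-batch training loss by half or more", {
  p <- histoPreset("easy")
  ds <- generateDataset(p$class1, p$class2, 4, c(64, 64), seed = 5)
  mod <- tinyModel(seed = 2)
  tr <- trainBackbone(mod, ds, epochs = 200, lr = 1e-3, batchSize = 8L,
                      seed = 3)
  expect_length(tr$loss, 200L)
  expect_lte(tr$loss[200], 0.5 * tr$loss[1])
})

test_that("weight archives round-trip, report renames, and reject bad shapes", {
  dir <- withr::local_tempdir()
  mod <- tinyModel(seed = 4)
  path <- file.path(dir, "w.json")
  saveWeights(mod, path)
  fresh <- tinyModel(seed = 99)
  res <- loadPretrained(fresh, path)
  expect_length(res$unmatchedModel, 0L)
  expect_length(res$unmatchedArchive, 0L)
  img <- randomTestImage(6, 64, 64)
  expect_equal(deepSmall(forwardFeatures(img, res$model)),
               deepSmall(forwardFeatures(img, mod)), tolerance = 1e-12)
  # one renamed tensor: reported unmatched, everything else loads
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  ren <- which(vapply(doc$tensors, `[[`, "", "name") == "small.cls")
  doc$tensors[[ren]]$name <- "small.cls_renamed"
  path2 <- file.path(dir, "w2.json")
  jsonlite::write_json(doc, path2, auto_unbox = TRUE, digits = NA)
  res2 <- loadPretrained(fresh, path2)
  expect_identical(res2$unmatchedArchive, "small.cls_renamed")
  expect_identical(res2$unmatchedModel, "small.cls")
  # wrong-shape patch embedding: error naming the tensor
  doc3 <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  emb <- which(vapply(doc3$tensors, `[[`, "", "name") == "small.embedW")
  doc3$tensors[[emb]]$shape <- c(10L, 10L)
  doc3$tensors[[emb]]$values <- rep(0, 100)
  path3 <- file.path(dir, "w3.json")
  jsonlite::write_json(doc3, path3, auto_unbox = TRUE, digits = NA)
  expect_error(loadPretrained(fresh, path3), "small.embedW")
})
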