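# Feature fusion and the feed-forward classifier.

gaussianClouds <- function(n, d = 10, sep = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 2L), each = n / 2)
  mu <- matrix(0, 2, d)
  mu[2, 1:2] <- sep                      # separation in units of the unit sd
  x <- matrix(rnorm(n * d), n, d) + mu[y, ]
  list(x = x, y = y)
}

test_that("fused vectors have the documented widths and recover their parts", {
  hand <- seq_len(818) / 818
  paper <- new("DeepFeatures", small = rnorm(384), large = rnorm(768))
  f <- fuseFeatures(paper, hand)
  expect_length(deepSmall(f), 1202L)
  expect_length(deepLarge(f), 1586L)
  expect_length(combinedFeatures(f), 2788L)
  expect_identical(deepSmall(f)[1:384], paper@small)
  expect_identical(unname(deepSmall(f)[385:1202]), unname(hand))
  expect_identical(deepLarge(f)[1:768], paper@large)
  expect_identical(combinedFeatures(f), c(deepSmall(f), deepLarge(f)))
  tiny <- new("DeepFeatures", small = rnorm(32), large = rnorm(64))
  ft <- fuseFeatures(tiny, hand)
  expect_length(deepSmall(ft), 850L)
  expect_length(deepLarge(ft), 882L)
  expect_error(fuseFeatures(paper, hand[-1]), "818")
})

test_that("the classifier separates well-separated Gaussian clouds", {
  tr <- gaussianClouds(200, seed = 1)
  va <- gaussianClouds(80, seed = 2)
  fit <- trainANN(tr$x, tr$y, va$x, va$y,
                  trainConfig(hiddenUnits = 32L, maxEpochs = 40L, seed = 7))
  pv <- predict(fit$model, va$x)
  expect_gte(mean(pv$labels == va$y), 0.95)
  pt <- predict(fit$model, tr$x)
  expect_gte(mean(pt$labels == tr$y), 0.99)
  expect_true(all(abs(rowSums(pv$prob) - 1) < 1e-6))
})

test_that("training histories are deterministic and internally consistent", {
  tr <- gaussianClouds(120, sep = 2, seed = 3)
  va <- gaussianClouds(60, sep = 2, seed = 4)
  cfgT <- trainConfig(hiddenUnits = 16L, maxEpochs = 25L, seed = 11)
  f1 <- trainANN(tr$x, tr$y, va$x, va$y, cfgT)
  f2 <- trainANN(tr$x, tr$y, va$x, va$y, cfgT)
  expect_identical(trainLoss(f1$history), trainLoss(f2$history))
  expect_identical(valLoss(f1$history), valLoss(f2$history))
  h <- f1$history
  expect_equal(bestValLoss(h), min(valLoss(h)))
  expect_equal(valLoss(h)[bestEpoch(h)], bestValLoss(h))
})

test_that("invalid training inputs are rejected and empty batches pass through", {
  tr <- gaussianClouds(40, seed = 5)
  va <- gaussianClouds(20, seed = 6)
  expect_error(trainANN(tr$x, rep(1L, 40), va$x, va$y, trainConfig()),
               "both classes")
  fit <- trainANN(tr$x, tr$y, va$x, va$y,
                  trainConfig(hiddenUnits = 8L, maxEpochs = 5L, seed = 2))
  expect_error(predict(fit$model, va$x[, 1:5]), "dimension")
  empty <- predict(fit$model, matrix(0, 0, ncol(tr$x)))
  expect_length(empty$labels, 0L)
  expect_length(empty$scores, 0L)
})

test_that("standardization statistics come from the training split only", {
  tr <- gaussianClouds(60, seed = 7)
  va <- gaussianClouds(30, seed = 8)
  va$x <- va$x + 100                      # shifted validation distribution
  fit <- trainANN(tr$x, tr$y, va$x, va$y,
                  trainConfig(hiddenUnits = 8L, maxEpochs = 3L, seed = 3))
  expect_equal(fit$model@center[[1]], colMeans(tr$x))
  expect_equal(fit$model@scale[[1]], apply(tr$x, 2, sd))
})

test_that("signal carried only by the handcrafted block survives fusion", {
  # deep block is pure noise; class signal lives in the last 20 columns
  set.seed(9)
  n <- 200; dDeep <- 30; dHand <- 20
  y <- rep(c(1L, 2L), each = n / 2)
  x <- cbind(matrix(rnorm(n * dDeep), n),
             matrix(rnorm(n * dHand), n) + ifelse(y == 2L, 3, 0))
  idx <- sample(n)
  trI <- idx[1:140]; vaI <- idx[141:200]
  fit <- trainANN(x[trI, ], y[trI], x[vaI, ], y[vaI],
                  trainConfig(hiddenUnits = 32L, maxEpochs = 40L, seed = 5))
  pv <- predict(fit$model, x[vaI, ])
  expect_gte(mean(pv$labels == y[vaI]), 0.9)
})

test_that("per-branch mode trains two networks and averages their logits", {
  tr <- gaussianClouds(120, d = 12, seed = 10)
  va <- gaussianClouds(60, d = 12, seed = 11)
  fit <- trainANN(tr$x, tr$y, va$x, va$y,
                  trainConfig(hiddenUnits = 16L, maxEpochs = 20L, seed = 2,
                              mode = "perbranch"), splitAt = 6L)
  expect_length(fit$model@nets, 2L)
  pv <- predict(fit$model, va$x)
  expect_gte(mean(pv$labels == va$y), 0.9)
  # archives round-trip the per-branch model
  dir <- withr::local_tempdir()
  saveFusionANN(fit$model, file.path(dir, "ann.json"))
  back <- loadFusionANN(file.path(dir, "ann.json"))
  pv2 <- predict(back, va$x)
  expect_equal(pv2$scores, pv$scores, tolerance = 1e-12)
})
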