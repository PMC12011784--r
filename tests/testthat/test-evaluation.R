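# Confusion counts, scalar metrics, ROC/AUC.

test_that("confusion counts tally items exactly", {
  expect_identical(confusionCounts(c(2, 2, 1, 1), c(2, 2, 1, 1)),
                   c(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  expect_identical(confusionCounts(c(2, 2, 1, 1), c(1, 1, 2, 2)),
                   c(TP = 0L, FP = 2L, TN = 0L, FN = 2L))
  set.seed(4)
  yt <- sample(1:2, 1000, replace = TRUE)
  yp <- sample(1:2, 1000, replace = TRUE)
  want <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (i in seq_along(yt)) {                      # item-by-item oracle
    k <- if (yt[i] == 2 && yp[i] == 2) "TP" else
         if (yt[i] == 1 && yp[i] == 2) "FP" else
         if (yt[i] == 1 && yp[i] == 1) "TN" else "FN"
    want[k] <- want[k] + 1L
  }
  expect_identical(confusionCounts(yt, yp), want)
  expect_error(confusionCounts(c(1, 2), c(1, 2, 1)), "equal length")
  expect_error(confusionCounts(c(1, 3), c(1, 1)), "labels")
})

test_that("scalar metrics reproduce the worked confusion matrix", {
  m <- scalarMetrics(c(TP = 40, FN = 10, FP = 5, TN = 45))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.80)
  expect_equal(m$specificity, 0.90)
  expect_equal(m$precision, 40 / 45)
  expect_equal(m$kappa, 0.70)             # p_o = 0.85, p_e = 0.5
  expect_equal(m$f1, 2 * (40 / 45) * 0.8 / (40 / 45 + 0.8))
})

test_that("perfect and fully inverted classifiers hit the metric extremes", {
  perfect <- scalarMetrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1, precision = 1, kappa = 1,
                                  f1 = 1))
  inverted <- scalarMetrics(c(TP = 0, TN = 0, FP = 50, FN = 50))
  expect_equal(inverted$accuracy, 0)
  expect_equal(inverted$kappa, -1)        # p_o = 0, p_e = 0.5
  expect_error(scalarMetrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("zero-denominator conventions return 0 with a warning flag", {
  m <- scalarMetrics(c(TP = 0, FN = 0, FP = 0, TN = 10))
  expect_equal(m$sensitivity, 0)
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
  expect_equal(m$kappa, 0)                # p_e = 1 with one observed class
  expect_setequal(attr(m, "warnings"),
                  c("sensitivity", "precision", "f1", "kappa"))
})

test_that("the F1 identity 2TP/(2TP+FP+FN) holds on random counts", {
  set.seed(7)
  for (i in 1:1000) {
    counts <- c(TP = sample(0:50, 1), FP = sample(0:50, 1),
                TN = sample(1:50, 1), FN = sample(0:50, 1))
    m <- scalarMetrics(counts)
    denom <- 2 * counts["TP"] + counts["FP"] + counts["FN"]
    if (m$precision + m$sensitivity > 0 && denom > 0)
      expect_equal(m$f1, unname(2 * counts["TP"] / denom), tolerance = 1e-12)
  }
})

test_that("kappa is 1 exactly when both classes occur without errors", {
  expect_equal(scalarMetrics(c(TP = 3, TN = 7, FP = 0, FN = 0))$kappa, 1)
  expect_lt(scalarMetrics(c(TP = 3, TN = 7, FP = 1, FN = 0))$kappa, 1)
})

test_that("ROC/AUC hits the extremes and matches the pairwise oracle", {
  y <- rep(c(1L, 2L), each = 5)
  expect_equal(rocAuc(y, c(1:5 / 10, 6:10 / 10))$auc, 1)
  expect_equal(rocAuc(y, c(6:10 / 10, 1:5 / 10))$auc, 0)
  set.seed(12)
  yr <- sample(1:2, 50, replace = TRUE)
  yr[1:2] <- 1:2                          # ensure both classes
  sc <- round(runif(50), 2)               # rounded scores force ties
  roc <- rocAuc(yr, sc)
  expect_equal(roc$auc, oracleAUC(yr, sc), tolerance = 1e-9)
  expect_true(all(diff(roc$curve$fpr) >= 0))
  expect_equal(roc$curve$fpr[1], 0)
  expect_equal(roc$curve$tpr[nrow(roc$curve)], 1)
  # independent library cross-check
  expect_equal(roc$auc,
               as.numeric(pROC::auc(pROC::roc(yr, sc, levels = c(1, 2),
                                              direction = "<",
                                              quiet = TRUE))),
               tolerance = 1e-9)
  expect_error(rocAuc(rep(1L, 10), runif(10)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  y <- c(1L, 2L, sample(1:2, 30, replace = TRUE))
  sc <- rnorm(32)
  a0 <- rocAuc(y, sc)$auc
  expect_equal(rocAuc(y, exp(sc))$auc, a0, tolerance = 1e-12)
  expect_equal(rocAuc(y, 5 * sc - 2)$auc, a0, tolerance = 1e-12)
})

test_that("the full report combines counts and the seven metrics", {
  y <- c(1L, 1L, 2L, 2L, 2L)
  p <- c(1L, 2L, 2L, 2L, 1L)
  s <- c(0.1, 0.6, 0.8, 0.9, 0.4)
  rep <- metricsReport(y, p, s)
  expect_identical(rep$counts, c(TP = 2L, FP = 1L, TN = 1L, FN = 1L))
  expect_equal(rep$accuracy, 0.6)
  expect_equal(rep$auc, rocAuc(y, s)$auc)
})
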