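# Deep + handcrafted feature fusion and the feed-forward fusion classifier.

#' TrainConfig: training configuration for the fusion classifier
#'
#' @slot hiddenUnits hidden layer width.
#' @slot maxEpochs maximum training epochs (>= 1).
#' @slot learningRate Adam learning rate.
#' @slot batchSize minibatch size.
#' @slot patience early-stopping patience (epochs without validation
#'   improvement; at most `maxEpochs`).
#' @slot seed integer RNG seed.
#' @slot standardize standardize features with train-split statistics.
#' @slot mode `"joint"` (one network on the combined vector, the default) or
#'   `"perbranch"` (one network per branch-fused vector, logits averaged).
#' @export
setClass("TrainConfig",
  representation(hiddenUnits = "integer", maxEpochs = "integer",
                 learningRate = "numeric", batchSize = "integer",
                 patience = "integer", seed = "integer",
                 standardize = "logical", mode = "character"),
  validity = function(object) {
    if (object@maxEpochs < 1L) return("maxEpochs must be >= 1")
    if (object@patience > object@maxEpochs)
      return("patience must be <= maxEpochs")
    if (!object@mode %in% c("joint", "perbranch"))
      return("mode must be 'joint' or 'perbranch'")
    TRUE
  }
)

#' Construct a TrainConfig
#'
#' @param hiddenUnits hidden layer width (default 128).
#' @param maxEpochs maximum epochs (default 100).
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param patience early-stopping patience in epochs; defaults to 20 capped
#'   at `maxEpochs`.
#' @param seed integer seed.
#' @param standardize standardize features on train-split statistics.
#' @param mode `"joint"` or `"perbranch"`.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(hiddenUnits = 128L, maxEpochs = 100L,
                        learningRate = 1e-3, batchSize = 32L,
                        patience = NULL, seed = 1L, standardize = TRUE,
                        mode = "joint") {
  if (is.null(patience)) patience <- min(20L, as.integer(maxEpochs))
  new("TrainConfig", hiddenUnits = as.integer(hiddenUnits),
      maxEpochs = as.integer(maxEpochs), learningRate = learningRate,
      batchSize = as.integer(batchSize), patience = as.integer(patience),
      seed = as.integer(seed), standardize = isTRUE(standardize),
      mode = mode)
}

#' Fuse deep CLS features with the handcrafted vector
#'
#' Per branch the deep CLS vector comes first, then the 818-dim handcrafted
#' vector; `combined` concatenates the small-branch then large-branch fused
#' vectors. Under the paper-preset widths (384/768) the branch vectors have
#' 1,202 and 1,586 entries.
#'
#' @param deep a [DeepFeatures-class].
#' @param hand numeric handcrafted vector of length 818.
#' @return a [FusedFeatures-class].
#' @export
fuseFeatures <- function(deep, hand) {
  stopifnot(is(deep, "DeepFeatures"))
  if (length(hand) != 818L)
    stop("handcrafted vector must have length 818, got ", length(hand))
  s <- c(deep@small, as.numeric(hand))
  l <- c(deep@large, as.numeric(hand))
  new("FusedFeatures", small = s, large = l, combined = c(s, l))
}

#' Fused feature matrix for a dataset
#'
#' Runs the backbone and the three handcrafted extractors on every image and
#' returns the combined fused vectors as rows.
#'
#' @param dataset a [HistoDataset-class].
#' @param model a [CrossViT-class].
#' @return numeric matrix, one row per image; attribute `splitAt` gives the
#'   length of the small-branch fused block.
#' @export
fusedMatrix <- function(dataset, model) {
  stopifnot(is(dataset, "HistoDataset"), is(model, "CrossViT"))
  rows <- lapply(images(dataset), function(img) {
    fused <- fuseFeatures(forwardFeatures(img, model), handcraftedVector(img))
    fused@combined
  })
  out <- do.call(rbind, rows)
  ds <- model@config@dimSmall
  dl <- model@config@dimLarge
  hn <- c(sprintf("fch_%03d", 0:767), sprintf("lbp_%02d", 0:25),
          sprintf("glcm_%02d", 0:23))
  colnames(out) <- c(sprintf("s_deep_%03d", seq_len(ds) - 1L),
                     paste0("s_", hn),
                     sprintf("l_deep_%03d", seq_len(dl) - 1L),
                     paste0("l_", hn))
  attr(out, "splitAt") <- ds + 818L
  out
}

# ---- single-hidden-layer perceptron internals ------------------------------

.mlpInit <- function(d, hidden, nClasses = 2L) {
  list(W1 = .randMat(d, hidden, sqrt(2 / d)), b1 = rep(0, hidden),
       W2 = .randMat(hidden, nClasses, sqrt(2 / hidden)),
       b2 = rep(0, nClasses))
}

.mlpLogits <- function(X, p) {
  H <- pmax(.linear(X, p$W1, p$b1), 0)
  list(logits = .linear(H, p$W2, p$b2), H = H)
}

.softmaxCE <- function(logits, y) {
  P <- .softmaxRows(logits)
  list(loss = -mean(log(pmax(P[cbind(seq_len(nrow(P)), y)], 1e-12))), P = P)
}

.standardizeFit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.standardizeApply <- function(X, st) {
  sweep(sweep(X, 2, st$center, `-`), 2, st$scale, `/`)
}

#' Train the fusion classifier
#'
#' A single-hidden-layer perceptron (rectified-linear activation, 2-class
#' softmax output) trained with minibatch Adam on cross-entropy. Optional
#' per-feature standardization is fitted on the training split only and
#' reused verbatim for validation and prediction. Training tracks the full
#' validation cross-entropy each epoch, stops early after `patience` epochs
#' without improvement, and returns the parameter snapshot of the best
#' validation epoch. Deterministic for a fixed config seed.
#'
#' In `"perbranch"` mode two such networks are trained -- one per branch
#' slice of the feature matrix (columns split at `splitAt`) -- and their
#' logits are averaged, mirroring the backbone's own logit fusion.
#'
#' @param features numeric training feature matrix (rows = items).
#' @param labelsTrain integer class codes in `{1, 2}`; both must occur.
#' @param valFeatures,valLabels validation split.
#' @param config a [TrainConfig-class].
#' @param splitAt column index ending the small-branch block (required for
#'   `"perbranch"` mode; taken from `attr(features, "splitAt")` if present).
#' @return list with `model` (a [FusionANN-class]) and `history`
#'   (a [TrainHistory-class]).
#' @export
trainANN <- function(features, labelsTrain, valFeatures, valLabels,
                     config = trainConfig(), splitAt = NULL) {
  stopifnot(is(config, "TrainConfig"))
  features <- as.matrix(features)
  valFeatures <- as.matrix(valFeatures)
  labelsTrain <- as.integer(labelsTrain)
  valLabels <- as.integer(valLabels)
  if (length(unique(labelsTrain)) < 2L)
    stop("training labels must contain both classes")
  if (ncol(valFeatures) != ncol(features))
    stop("validation features must match training feature dimension")
  if (is.null(splitAt)) splitAt <- attr(features, "splitAt")
  nets <- if (config@mode == "joint") {
    list(seq_len(ncol(features)))
  } else {
    if (is.null(splitAt) || splitAt < 1L || splitAt >= ncol(features))
      stop("perbranch mode needs a valid splitAt column index")
    list(seq_len(splitAt), (splitAt + 1L):ncol(features))
  }
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(config@seed %% 2147483647L, kind = "Mersenne-Twister",
           normal.kind = "Inversion")

  sts <- lapply(nets, function(colsIdx) {
    if (config@standardize) .standardizeFit(features[, colsIdx, drop = FALSE])
    else list(center = rep(0, length(colsIdx)),
              scale = rep(1, length(colsIdx)))
  })
  Xtr <- lapply(seq_along(nets), function(i)
    .standardizeApply(features[, nets[[i]], drop = FALSE], sts[[i]]))
  Xval <- lapply(seq_along(nets), function(i)
    .standardizeApply(valFeatures[, nets[[i]], drop = FALSE], sts[[i]]))
  ps <- lapply(nets, function(colsIdx)
    .mlpInit(length(colsIdx), config@hiddenUnits))

  fwdAll <- function(Xs, ps) {
    outs <- lapply(seq_along(ps), function(i) .mlpLogits(Xs[[i]], ps[[i]]))
    logits <- Reduce(`+`, lapply(outs, `[[`, "logits")) / length(outs)
    list(logits = logits, outs = outs)
  }

  mS <- lapply(ps, .zeroLike)
  vS <- lapply(ps, .zeroLike)
  b1m <- 0.9; b2m <- 0.999; epsA <- 1e-8; tA <- 0
  n <- nrow(features)
  trainCurve <- valCurve <- numeric(0)
  bestVal <- Inf; bestPs <- ps; bestEp <- 0L
  for (ep in seq_len(config@maxEpochs)) {
    ord <- sample.int(n)
    epochLoss <- 0; nb <- 0
    for (start in seq(1, n, by = config@batchSize)) {
      idx <- ord[start:min(start + config@batchSize - 1L, n)]
      Xb <- lapply(Xtr, function(X) X[idx, , drop = FALSE])
      yb <- labelsTrain[idx]
      fw <- fwdAll(Xb, ps)
      ce <- .softmaxCE(fw$logits, yb)
      epochLoss <- epochLoss + ce$loss; nb <- nb + 1
      dLogits <- ce$P
      dLogits[cbind(seq_along(yb), yb)] <-
        dLogits[cbind(seq_along(yb), yb)] - 1
      dLogits <- dLogits / (length(yb) * length(ps))
      grads <- lapply(seq_along(ps), function(i) {
        H <- fw$outs[[i]]$H
        dW2 <- t(H) %*% dLogits
        db2 <- colSums(dLogits)
        dH <- (dLogits %*% t(ps[[i]]$W2)) * (H > 0)
        list(W1 = t(Xb[[i]]) %*% dH, b1 = colSums(dH), W2 = dW2, b2 = db2)
      })
      tA <- tA + 1
      for (i in seq_along(ps)) {
        mS[[i]] <- .mapTensors(function(m, g) b1m * m + (1 - b1m) * g,
                               mS[[i]], grads[[i]])
        vS[[i]] <- .mapTensors(function(v, g) b2m * v + (1 - b2m) * g^2,
                               vS[[i]], grads[[i]])
        ps[[i]] <- .mapTensors(function(p, m, v)
          p - config@learningRate * (m / (1 - b1m^tA)) /
            (sqrt(v / (1 - b2m^tA)) + epsA),
          ps[[i]], mS[[i]], vS[[i]])
      }
    }
    trainCurve <- c(trainCurve, epochLoss / nb)
    vl <- .softmaxCE(fwdAll(Xval, ps)$logits, valLabels)$loss
    valCurve <- c(valCurve, vl)
    if (vl < bestVal) {
      bestVal <- vl; bestPs <- ps; bestEp <- ep
    }
    if (ep - bestEp >= config@patience) break
  }
  model <- new("FusionANN", nets = bestPs,
               inputDims = vapply(nets, length, integer(1)),
               inputOffsets = vapply(nets, function(ix) ix[1] - 1L,
                                     integer(1)),
               center = lapply(sts, `[[`, "center"),
               scale = lapply(sts, `[[`, "scale"),
               standardize = config@standardize, mode = config@mode)
  history <- new("TrainHistory", trainLoss = trainCurve, valLoss = valCurve,
                 bestEpoch = bestEp, bestValLoss = bestVal)
  list(model = model, history = history)
}

#' Predict with a trained fusion classifier
#'
#' @param object a [FusionANN-class].
#' @param newdata numeric feature matrix (rows = items); may have zero rows.
#' @param ... ignored.
#' @return list with `labels` (class codes 1/2; exact probability ties go to
#'   class 1) and `scores` (probability of class 2, the malignant class).
#' @export
setMethod("predict", "FusionANN", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  need <- sum(object@inputDims)
  if (ncol(X) != need && !(object@mode == "joint" &&
                           ncol(X) == object@inputDims[1]))
    stop("feature dimension ", ncol(X), " does not match the trained model (",
         need, ")")
  if (nrow(X) == 0L)
    return(list(labels = integer(0), scores = numeric(0),
                prob = matrix(numeric(0), 0, 2)))
  logits <- 0
  for (i in seq_along(object@nets)) {
    cols <- object@inputOffsets[i] + seq_len(object@inputDims[i])
    Xi <- X[, cols, drop = FALSE]
    if (object@standardize)
      Xi <- .standardizeApply(Xi, list(center = object@center[[i]],
                                       scale = object@scale[[i]]))
    logits <- logits + .mlpLogits(Xi, object@nets[[i]])$logits
  }
  logits <- logits / length(object@nets)
  P <- .softmaxRows(logits)
  labels <- ifelse(P[, 2] > P[, 1], 2L, 1L)   # exact tie -> class 1
  list(labels = as.integer(labels), scores = P[, 2], prob = P)
})
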