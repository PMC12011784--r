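# Reverse-mode gradients and optimization for the backbone.
#
# The forward pass is re-implemented here with caching of every intermediate
# (token states, attention maps, layer-norm statistics), and each layer has a
# hand-written backward. Gradients are accumulated in double precision and
# averaged over the minibatch; the optimizer is Adam.

# apply f over parallel nested parameter structures, leaf by leaf
.mapTensors <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- lapply(seq_along(args[[1]]), function(i)
      do.call(.mapTensors, c(list(f), lapply(args, `[[`, i))))
    names(out) <- names(args[[1]])
    out
  } else {
    do.call(f, args)
  }
}

.zeroLike <- function(params) .mapTensors(function(x) x * 0, params)

# ---- cached forward / backward primitives ----------------------------------

.fwdLN <- function(X, g, b, eps = 1e-6) {
  m <- rowMeans(X)
  xc <- X - m
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(out = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv, g = g)
}

.bwdLN <- function(dY, cache) {
  D <- ncol(dY)
  dxhat <- dY * rep(cache$g, each = nrow(dY))
  s1 <- rowSums(dxhat) / D
  s2 <- rowSums(dxhat * cache$xhat) / D
  dX <- cache$inv * (dxhat - s1 - cache$xhat * s2)
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

.fwdMSA <- function(Xn, p, heads) {
  Tn <- nrow(Xn); D <- ncol(Xn); dk <- D %/% heads
  Q <- .linear(Xn, p$Wq, p$bq)
  K <- .linear(Xn, p$Wk, p$bk)
  V <- .linear(Xn, p$Wv, p$bv)
  O <- matrix(0, Tn, D)
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    A[[h]] <- .softmaxRows(Q[, cols, drop = FALSE] %*%
                             t(K[, cols, drop = FALSE]) / sqrt(dk))
    O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
  }
  list(out = .linear(O, p$Wo, p$bo), Xn = Xn, Q = Q, K = K, V = V, O = O,
       A = A, heads = heads, dk = dk)
}

.bwdMSA <- function(dOut, cache, p) {
  dWo <- t(cache$O) %*% dOut
  dbo <- colSums(dOut)
  dO <- dOut %*% t(p$Wo)
  dQ <- dK <- dV <- matrix(0, nrow(dOut), ncol(dOut))
  for (h in seq_len(cache$heads)) {
    cols <- ((h - 1L) * cache$dk + 1L):(h * cache$dk)
    Ah <- cache$A[[h]]
    Vh <- cache$V[, cols, drop = FALSE]
    dOh <- dO[, cols, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, cols] <- t(Ah) %*% dOh
    dS <- (dA - rowSums(dA * Ah)) * Ah / sqrt(cache$dk)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- t(dS) %*% cache$Q[, cols, drop = FALSE]
  }
  Xn <- cache$Xn
  list(dXn = dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv),
       grads = list(Wq = t(Xn) %*% dQ, bq = colSums(dQ),
                    Wk = t(Xn) %*% dK, bk = colSums(dK),
                    Wv = t(Xn) %*% dV, bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

.fwdEncoder <- function(x, p, heads) {
  ln1 <- .fwdLN(x, p$ln1g, p$ln1b)
  msa <- .fwdMSA(ln1$out, p, heads)
  y <- x + msa$out
  ln2 <- .fwdLN(y, p$ln2g, p$ln2b)
  pre <- .linear(ln2$out, p$W1, p$b1)
  act <- .gelu(pre)
  out <- y + .linear(act, p$W2, p$b2)
  list(out = out, ln1 = ln1, msa = msa, ln2 = ln2, pre = pre, act = act)
}

.bwdEncoder <- function(dOut, cache, p) {
  dY <- dOut
  dW2 <- t(cache$act) %*% dOut
  db2 <- colSums(dOut)
  dact <- dOut %*% t(p$W2)
  dpre <- dact * (stats::pnorm(cache$pre) +
                    cache$pre * stats::dnorm(cache$pre))
  dW1 <- t(cache$ln2$out) %*% dpre
  db1 <- colSums(dpre)
  bl2 <- .bwdLN(dpre %*% t(p$W1), cache$ln2)
  dY <- dY + bl2$dX
  bm <- .bwdMSA(dY, cache$msa, p)
  bl1 <- .bwdLN(bm$dXn, cache$ln1)
  grads <- c(bm$grads,
             list(ln1g = bl1$dg, ln1b = bl1$db, ln2g = bl2$dg, ln2b = bl2$db,
                  W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
  list(dX = dY + bl1$dX, grads = grads[c("ln1g", "ln1b", "Wq", "bq", "Wk",
                                         "bk", "Wv", "bv", "Wo", "bo",
                                         "ln2g", "ln2b", "W1", "b1", "W2",
                                         "b2")])
}

.fwdCross <- function(cls, patches, p) {
  f <- .linear(matrix(cls, 1), p$Wf, p$bf)
  xp <- rbind(f, patches)
  ln <- .fwdLN(xp, p$lng, p$lnb)
  xn <- ln$out
  q <- .linear(xn[1, , drop = FALSE], p$Wq, p$bq)
  k <- .linear(xn, p$Wk, p$bk)
  v <- .linear(xn, p$Wv, p$bv)
  sc <- 1 / sqrt(ncol(k))
  att <- .softmaxRows(q %*% t(k) * sc)
  list(out = cls + as.numeric(att %*% v), cls = cls, ln = ln, xn = xn,
       q = q, k = k, v = v, att = att, sc = sc)
}

.bwdCross <- function(dOut, cache, p) {
  dOut <- matrix(dOut, 1)
  dcls <- as.numeric(dOut)                    # residual path
  dA <- dOut %*% t(cache$v)
  dv <- t(cache$att) %*% dOut
  dS <- (dA - sum(dA * cache$att)) * cache$att * cache$sc
  dq <- dS %*% cache$k
  dk <- t(dS) %*% cache$q
  xn <- cache$xn
  dWv <- t(xn) %*% dv; dbv <- colSums(dv)
  dWk <- t(xn) %*% dk; dbk <- colSums(dk)
  dWq <- t(xn[1, , drop = FALSE]) %*% dq; dbq <- as.numeric(dq)
  dxn <- dv %*% t(p$Wv) + dk %*% t(p$Wk)
  dxn[1, ] <- dxn[1, ] + as.numeric(dq %*% t(p$Wq))
  bl <- .bwdLN(dxn, cache$ln)
  dxp <- bl$dX
  df <- dxp[1, , drop = FALSE]
  dpatches <- dxp[-1, , drop = FALSE]
  dWf <- t(matrix(cache$cls, 1)) %*% df
  dcls <- dcls + as.numeric(df %*% t(p$Wf))
  list(dcls = dcls, dpatches = dpatches,
       grads = list(Wf = dWf, bf = as.numeric(df), lng = bl$dg, lnb = bl$db,
                    Wq = dWq, bq = dbq, Wk = dWk, bk = dbk, Wv = dWv,
                    bv = dbv))
}

.patchify <- function(image, patch) {
  d <- dim(image)
  n <- d[1] %/% patch
  px <- image@.Data / 255
  P <- matrix(0, n * n, patch * patch * 3L)
  for (gy in seq_len(n)) for (gx in seq_len(n)) {
    rows <- ((gy - 1L) * patch + 1L):(gy * patch)
    cols <- ((gx - 1L) * patch + 1L):(gx * patch)
    P[(gy - 1L) * n + gx, ] <- as.numeric(px[rows, cols, ])
  }
  P
}

# cached full forward of one image up to the fused logits
.fwdModel <- function(image, params, cfg) {
  Ps <- .patchify(image, cfg@patchSmall)
  Pl <- .patchify(image, cfg@patchLarge)
  ts <- rbind(params$small$cls,
              .linear(Ps, params$small$embedW, params$small$embedB)) +
    params$small$pos
  tl <- rbind(params$large$cls,
              .linear(Pl, params$large$embedW, params$large$embedB)) +
    params$large$pos
  encS <- encL <- vector("list", cfg@depth)
  for (k in seq_len(cfg@depth)) {
    encS[[k]] <- .fwdEncoder(ts, params$small$layers[[k]], cfg@heads)
    ts <- encS[[k]]$out
    encL[[k]] <- .fwdEncoder(tl, params$large$layers[[k]], cfg@heads)
    tl <- encL[[k]]$out
  }
  crossCache <- vector("list", cfg@nCrossRounds)
  for (r in seq_len(cfg@nCrossRounds)) {
    cL <- .fwdCross(tl[1, ], ts[-1, , drop = FALSE],
                    params$cross[[r]]$largeFromSmall)
    cS <- .fwdCross(ts[1, ], tl[-1, , drop = FALSE],
                    params$cross[[r]]$smallFromLarge)
    crossCache[[r]] <- list(L = cL, S = cS)
    tl[1, ] <- cL$out
    ts[1, ] <- cS$out
  }
  lnS <- .fwdLN(ts[1, , drop = FALSE], params$small$lnFg, params$small$lnFb)
  lnL <- .fwdLN(tl[1, , drop = FALSE], params$large$lnFg, params$large$lnFb)
  zs <- as.numeric(lnS$out)
  zl <- as.numeric(lnL$out)
  logS <- as.numeric(zs %*% params$headSmall$W + params$headSmall$b)
  logL <- as.numeric(zl %*% params$headLarge$W + params$headLarge$b)
  list(fused = (logS + logL) / 2, zs = zs, zl = zl, Ps = Ps, Pl = Pl,
       encS = encS, encL = encL, crossCache = crossCache, lnS = lnS,
       lnL = lnL)
}

# backward from d(fused logits); returns gradients shaped like params
.bwdModel <- function(fw, dFused, params, cfg) {
  g <- .zeroLike(params)
  dHalf <- dFused / 2
  g$headSmall$W <- t(matrix(fw$zs, 1)) %*% matrix(dHalf, 1)
  g$headSmall$b <- dHalf
  g$headLarge$W <- t(matrix(fw$zl, 1)) %*% matrix(dHalf, 1)
  g$headLarge$b <- dHalf
  dzs <- matrix(as.numeric(params$headSmall$W %*% dHalf), 1)
  dzl <- matrix(as.numeric(params$headLarge$W %*% dHalf), 1)
  blS <- .bwdLN(dzs, fw$lnS)
  blL <- .bwdLN(dzl, fw$lnL)
  g$small$lnFg <- blS$dg; g$small$lnFb <- blS$db
  g$large$lnFg <- blL$dg; g$large$lnFb <- blL$db

  nTs <- nrow(fw$encS[[cfg@depth]]$out)
  nTl <- nrow(fw$encL[[cfg@depth]]$out)
  dts <- matrix(0, nTs, cfg@dimSmall)
  dtl <- matrix(0, nTl, cfg@dimLarge)
  dts[1, ] <- blS$dX
  dtl[1, ] <- blL$dX
  for (r in rev(seq_len(cfg@nCrossRounds))) {
    cc <- fw$crossCache[[r]]
    dNewL <- dtl[1, ]
    dNewS <- dts[1, ]
    dts[1, ] <- 0
    dtl[1, ] <- 0
    bL <- .bwdCross(dNewL, cc$L, .paramsCross(params, r)$largeFromSmall)
    bS <- .bwdCross(dNewS, cc$S, .paramsCross(params, r)$smallFromLarge)
    g$cross[[r]]$largeFromSmall <- .mapTensors(`+`,
      g$cross[[r]]$largeFromSmall, bL$grads)
    g$cross[[r]]$smallFromLarge <- .mapTensors(`+`,
      g$cross[[r]]$smallFromLarge, bS$grads)
    dtl[1, ] <- dtl[1, ] + bL$dcls
    dts[1, ] <- dts[1, ] + bS$dcls
    dts[-1, ] <- dts[-1, , drop = FALSE] + bL$dpatches
    dtl[-1, ] <- dtl[-1, , drop = FALSE] + bS$dpatches
  }
  for (k in rev(seq_len(cfg@depth))) {
    bs <- .bwdEncoder(dts, fw$encS[[k]], params$small$layers[[k]])
    g$small$layers[[k]] <- bs$grads
    dts <- bs$dX
    bl <- .bwdEncoder(dtl, fw$encL[[k]], params$large$layers[[k]])
    g$large$layers[[k]] <- bl$grads
    dtl <- bl$dX
  }
  g$small$pos <- dts
  g$small$cls <- dts[1, ]
  g$small$embedW <- t(fw$Ps) %*% dts[-1, , drop = FALSE]
  g$small$embedB <- colSums(dts[-1, , drop = FALSE])
  g$large$pos <- dtl
  g$large$cls <- dtl[1, ]
  g$large$embedW <- t(fw$Pl) %*% dtl[-1, , drop = FALSE]
  g$large$embedB <- colSums(dtl[-1, , drop = FALSE])
  g
}

.paramsCross <- function(params, r) params$cross[[r]]

# mean cross-entropy and mean gradients over a batch of images
.batchLossGrad <- function(imagesList, labels, params, cfg,
                           wantGrad = TRUE) {
  n <- length(imagesList)
  loss <- 0
  g <- if (wantGrad) .zeroLike(params) else NULL
  for (i in seq_len(n)) {
    fw <- .fwdModel(imagesList[[i]], params, cfg)
    z <- fw$fused - max(fw$fused)
    p <- exp(z) / sum(exp(z))
    loss <- loss - log(max(p[labels[i]], 1e-12))
    if (wantGrad) {
      dFused <- p
      dFused[labels[i]] <- dFused[labels[i]] - 1
      g <- .mapTensors(`+`, g, .bwdModel(fw, dFused / n, params, cfg))
    }
  }
  list(loss = loss / n, grads = g)
}

#' Train the backbone with Adam on cross-entropy
#'
#' Minibatch gradient descent on the fused-logit cross-entropy with
#' hand-derived reverse-mode gradients for every parameter (patch embeddings,
#' positional encodings, encoder layers, cross-attention blocks, final layer
#' norms and heads). Deterministic for a fixed seed.
#'
#' @param model a [CrossViT-class].
#' @param dataset a [HistoDataset-class] whose images match the model input
#'   size.
#' @param epochs passes over the data.
#' @param lr Adam learning rate.
#' @param batchSize minibatch size.
#' @param seed integer seed controlling the minibatch shuffle.
#' @return list with `model` (updated [CrossViT-class]) and `loss` (the
#'   per-step training cross-entropy trace).
#' @export
trainBackbone <- function(model, dataset, epochs = 3, lr = 1e-3,
                          batchSize = 8L, seed = 1L) {
  stopifnot(is(model, "CrossViT"), is(dataset, "HistoDataset"))
  if (length(unique(imageLabels(dataset))) < 2L)
    stop("training data must contain both classes")
  cfg <- model@config
  params <- model@params
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(as.integer(seed) %% 2147483647L, kind = "Mersenne-Twister")
  mState <- .zeroLike(params)
  vState <- .zeroLike(params)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t0 <- 0
  trace <- numeric(0)
  imgs <- images(dataset)
  labs <- imageLabels(dataset)
  n <- length(imgs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      lg <- .batchLossGrad(imgs[idx], labs[idx], params, cfg)
      trace <- c(trace, lg$loss)
      t0 <- t0 + 1
      mState <- .mapTensors(function(m, g) b1 * m + (1 - b1) * g,
                            mState, lg$grads)
      vState <- .mapTensors(function(v, g) b2 * v + (1 - b2) * g^2,
                            vState, lg$grads)
      corr1 <- 1 - b1^t0
      corr2 <- 1 - b2^t0
      params <- .mapTensors(function(p, m, v)
        p - lr * (m / corr1) / (sqrt(v / corr2) + eps),
        params, mState, vState)
    }
  }
  list(model = new("CrossViT", config = cfg, params = params), loss = trace)
}
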