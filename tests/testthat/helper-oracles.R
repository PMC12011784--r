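# Independent reference implementations written as explicit scalar loops.
# They deliberately share no code with the package internals.

randomTestImage <- function(seed, h = 16, w = 16) {
  set.seed(seed)
  RGBImage(array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3)))
}

oracleLayerNorm <- function(X, g, b, eps = 1e-6) {
  out <- X
  for (i in seq_len(nrow(X))) {
    m <- mean(X[i, ])
    v <- mean((X[i, ] - m)^2)
    out[i, ] <- (X[i, ] - m) / sqrt(v + eps) * g + b
  }
  out
}

oracleLinearRow <- function(x, W, b) {
  out <- numeric(ncol(W))
  for (d in seq_len(ncol(W))) out[d] <- sum(x * W[, d]) + b[d]
  out
}

oracleSoftmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

# one encoder layer: Y = X + MSA(LN(X)); out = Y + FFN(LN(Y))
oracleEncoderLayer <- function(x, p, heads) {
  Tn <- nrow(x); D <- ncol(x); dk <- D / heads
  xn <- oracleLayerNorm(x, p$ln1g, p$ln1b)
  Q <- K <- V <- matrix(0, Tn, D)
  for (i in seq_len(Tn)) {
    Q[i, ] <- oracleLinearRow(xn[i, ], p$Wq, p$bq)
    K[i, ] <- oracleLinearRow(xn[i, ], p$Wk, p$bk)
    V[i, ] <- oracleLinearRow(xn[i, ], p$Wv, p$bv)
  }
  O <- matrix(0, Tn, D)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    for (i in seq_len(Tn)) {
      s <- numeric(Tn)
      for (j in seq_len(Tn)) s[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dk)
      a <- oracleSoftmax(s)
      for (j in seq_len(Tn)) O[i, cols] <- O[i, cols] + a[j] * V[j, cols]
    }
  }
  y <- x
  for (i in seq_len(Tn)) y[i, ] <- x[i, ] + oracleLinearRow(O[i, ], p$Wo, p$bo)
  yn <- oracleLayerNorm(y, p$ln2g, p$ln2b)
  out <- y
  for (i in seq_len(Tn)) {
    h1 <- oracleLinearRow(yn[i, ], p$W1, p$b1)
    h1 <- h1 * pnorm(h1)                       # GELU
    out[i, ] <- y[i, ] + oracleLinearRow(h1, p$W2, p$b2)
  }
  out
}

# cross-attention CLS update: x' = [f(cls) || patches]; single query from the
# projected CLS; softmax over 1 + N positions scaled by 1/sqrt(d_k); residual
oracleCrossAttention <- function(cls, patches, p) {
  f <- oracleLinearRow(cls, p$Wf, p$bf)
  xp <- rbind(f, patches)
  xn <- oracleLayerNorm(xp, p$lng, p$lnb)
  q <- oracleLinearRow(xn[1, ], p$Wq, p$bq)
  n <- nrow(xp)
  k <- v <- NULL
  s <- numeric(n)
  vs <- matrix(0, n, ncol(p$Wv))
  for (j in seq_len(n)) {
    kj <- oracleLinearRow(xn[j, ], p$Wk, p$bk)
    vs[j, ] <- oracleLinearRow(xn[j, ], p$Wv, p$bv)
    s[j] <- sum(q * kj) / sqrt(length(kj))
  }
  a <- oracleSoftmax(s)
  ctx <- numeric(ncol(vs))
  for (j in seq_len(n)) ctx <- ctx + a[j] * vs[j, ]
  cls + ctx
}

# full dual-branch forward pass, assembled from the loop-based pieces
oracleForwardFeatures <- function(image, model) {
  cfg <- model@config
  px <- image@.Data / 255
  embed <- function(patch, bp) {
    n <- cfg@imageSize %/% patch
    tok <- matrix(0, n * n + 1, ncol(bp$embedW))
    tok[1, ] <- bp$cls
    for (gy in seq_len(n)) for (gx in seq_len(n)) {
      vec <- numeric(0)
      for (ch in 1:3) for (xx in ((gx - 1) * patch + 1):(gx * patch))
        for (yy in ((gy - 1) * patch + 1):(gy * patch))
          vec <- c(vec, px[yy, xx, ch])
      tok[(gy - 1) * n + gx + 1, ] <- oracleLinearRow(vec, bp$embedW,
                                                      bp$embedB)
    }
    tok + bp$pos
  }
  ts <- embed(cfg@patchSmall, model@params$small)
  tl <- embed(cfg@patchLarge, model@params$large)
  for (k in seq_len(cfg@depth)) {
    ts <- oracleEncoderLayer(ts, model@params$small$layers[[k]], cfg@heads)
    tl <- oracleEncoderLayer(tl, model@params$large$layers[[k]], cfg@heads)
  }
  for (r in seq_len(cfg@nCrossRounds)) {
    newL <- oracleCrossAttention(tl[1, ], ts[-1, , drop = FALSE],
                                 model@params$cross[[r]]$largeFromSmall)
    newS <- oracleCrossAttention(ts[1, ], tl[-1, , drop = FALSE],
                                 model@params$cross[[r]]$smallFromLarge)
    tl[1, ] <- newL
    ts[1, ] <- newS
  }
  list(
    small = as.numeric(oracleLayerNorm(ts[1, , drop = FALSE],
                                       model@params$small$lnFg,
                                       model@params$small$lnFb)),
    large = as.numeric(oracleLayerNorm(tl[1, , drop = FALSE],
                                       model@params$large$lnFg,
                                       model@params$large$lnFb)))
}

# brute-force GLCM features: explicit loops over every pixel pair
oracleGLCM <- function(image) {
  px <- image@.Data
  g <- round(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
  q <- pmin(floor(g / 4), 63)
  H <- nrow(q); W <- ncol(q)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  out <- numeric(0)
  for (off in offs) {
    P <- matrix(0, 64, 64)
    for (r in seq_len(H)) for (c in seq_len(W)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W) {
        i <- q[r, c] + 1; j <- q[r2, c2] + 1
        P[i, j] <- P[i, j] + 1
        P[j, i] <- P[j, i] + 1
      }
    }
    P <- P / sum(P)
    contrast <- dissim <- homog <- energy <- entropy <- 0
    mu <- 0; lev <- 0:63
    pr <- rowSums(P)
    for (i in 1:64) mu <- mu + (i - 1) * pr[i]
    sig2 <- 0
    for (i in 1:64) sig2 <- sig2 + (i - 1 - mu)^2 * pr[i]
    corr <- 0
    for (i in 1:64) for (j in 1:64) {
      p <- P[i, j]
      d <- (i - j)
      contrast <- contrast + p * d^2
      dissim <- dissim + p * abs(d)
      homog <- homog + p / (1 + d^2)
      energy <- energy + p^2
      if (p > 0) entropy <- entropy - p * log(p)
      if (sig2 > 0) corr <- corr + (i - 1 - mu) * (j - 1 - mu) * p / sig2
    }
    out <- c(out, contrast, dissim, homog, energy, corr, entropy)
  }
  out
}

# Mann-Whitney pairwise concordance with ties counted one half
oracleAUC <- function(y, scores, positive = 2) {
  posIdx <- which(y == positive)
  negIdx <- which(y != positive)
  tot <- 0
  for (i in posIdx) for (j in negIdx) {
    tot <- tot + if (scores[i] > scores[j]) 1 else
      if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(posIdx) * length(negIdx))
}
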