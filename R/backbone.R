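# Dual-branch cross-attention vision transformer.
#
# Each branch embeds its own patch size, prepends a CLS token, adds a learned
# positional encoding, and runs a stack of pre-norm transformer encoder
# layers (multi-head self-attention + FFN, both residual). The branches then
# exchange information through bidirectional cross-attention: each branch's
# CLS token (projected into the other branch's width) queries the other
# branch's tokens and is updated with a residual add. The final per-branch
# CLS vectors are the deep features; two linear heads produce per-branch
# logits whose elementwise mean is the fused output.

#' Build a backbone configuration
#'
#' Two bundled presets: `"paper"` (image 240, patches 12/16, dims 384/768 --
#' the widths whose CLS features are fused downstream) and `"tiny"` (image
#' 64, patches 8/16, dims 32/64) for fast CPU work. Any field can be
#' overridden. Depth, heads, MLP ratio and the number of cross-attention
#' rounds are free choices of the architecture and default to compact values.
#'
#' @param preset `"paper"` or `"tiny"`.
#' @param imageSize,patchSmall,patchLarge,dimSmall,dimLarge,depth,heads
#'   optional overrides of the preset.
#' @param mlpRatio,nCrossRounds,nClasses optional overrides.
#' @return a [BackboneConfig-class].
#' @examples
#' backboneConfig("tiny")
#' @export
backboneConfig <- function(preset = c("tiny", "paper"), imageSize = NULL,
                           patchSmall = NULL, patchLarge = NULL,
                           dimSmall = NULL, dimLarge = NULL, depth = NULL,
                           heads = NULL, mlpRatio = NULL, nCrossRounds = NULL,
                           nClasses = NULL) {
  preset <- match.arg(preset)
  base <- if (preset == "paper") {
    list(imageSize = 240L, patchSmall = 12L, patchLarge = 16L,
         dimSmall = 384L, dimLarge = 768L, depth = 2L, heads = 6L,
         mlpRatio = 4, nCrossRounds = 1L, nClasses = 2L)
  } else {
    list(imageSize = 64L, patchSmall = 8L, patchLarge = 16L,
         dimSmall = 32L, dimLarge = 64L, depth = 2L, heads = 2L,
         mlpRatio = 2, nCrossRounds = 1L, nClasses = 2L)
  }
  ov <- list(imageSize = imageSize, patchSmall = patchSmall,
             patchLarge = patchLarge, dimSmall = dimSmall,
             dimLarge = dimLarge, depth = depth, heads = heads,
             mlpRatio = mlpRatio, nCrossRounds = nCrossRounds,
             nClasses = nClasses)
  for (nm in names(ov)) if (!is.null(ov[[nm]])) base[[nm]] <- ov[[nm]]
  new("BackboneConfig",
      imageSize = as.integer(base$imageSize),
      patchSmall = as.integer(base$patchSmall),
      patchLarge = as.integer(base$patchLarge),
      dimSmall = as.integer(base$dimSmall),
      dimLarge = as.integer(base$dimLarge),
      depth = as.integer(base$depth), heads = as.integer(base$heads),
      mlpRatio = as.numeric(base$mlpRatio),
      nCrossRounds = as.integer(base$nCrossRounds),
      nClasses = as.integer(base$nClasses))
}

.randMat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

.initEncoderLayer <- function(dim, hid) {
  s <- 0.02
  list(ln1g = rep(1, dim), ln1b = rep(0, dim),
       Wq = .randMat(dim, dim, s), bq = rep(0, dim),
       Wk = .randMat(dim, dim, s), bk = rep(0, dim),
       Wv = .randMat(dim, dim, s), bv = rep(0, dim),
       Wo = .randMat(dim, dim, s), bo = rep(0, dim),
       ln2g = rep(1, dim), ln2b = rep(0, dim),
       W1 = .randMat(dim, hid, s), b1 = rep(0, hid),
       W2 = .randMat(hid, dim, s), b2 = rep(0, dim))
}

.initBranch <- function(imageSize, patch, dim, depth, mlpRatio) {
  nTok <- (imageSize %/% patch)^2 + 1L
  pd <- patch * patch * 3L
  hid <- as.integer(round(dim * mlpRatio))
  list(embedW = .randMat(pd, dim, 0.02), embedB = rep(0, dim),
       cls = stats::rnorm(dim, 0, 0.02),
       pos = .randMat(nTok, dim, 0.02),
       layers = lapply(seq_len(depth), function(k) .initEncoderLayer(dim, hid)),
       lnFg = rep(1, dim), lnFb = rep(0, dim))
}

.initCross <- function(dimCls, dimPatch) {
  s <- 0.02
  list(Wf = .randMat(dimCls, dimPatch, s), bf = rep(0, dimPatch),
       lng = rep(1, dimPatch), lnb = rep(0, dimPatch),
       Wq = .randMat(dimPatch, dimPatch, s), bq = rep(0, dimPatch),
       Wk = .randMat(dimPatch, dimPatch, s), bk = rep(0, dimPatch),
       Wv = .randMat(dimPatch, dimCls, s), bv = rep(0, dimCls))
}

#' Initialize a CrossViT model
#'
#' All weight matrices are drawn from a small-variance Gaussian (sd 0.02,
#' fixed seed), biases zero, layer-norm scales one; positional encodings are
#' learned parameters with the same initialization.
#'
#' @param config a [BackboneConfig-class].
#' @param seed integer seed for the initialization draw.
#' @return a [CrossViT-class] model.
#' @export
crossViT <- function(config = backboneConfig("tiny"), seed = 1L) {
  stopifnot(is(config, "BackboneConfig"))
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(as.integer(seed) %% 2147483647L, kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  params <- list(
    small = .initBranch(config@imageSize, config@patchSmall, config@dimSmall,
                        config@depth, config@mlpRatio),
    large = .initBranch(config@imageSize, config@patchLarge, config@dimLarge,
                        config@depth, config@mlpRatio),
    cross = lapply(seq_len(config@nCrossRounds), function(r)
      list(largeFromSmall = .initCross(config@dimLarge, config@dimSmall),
           smallFromLarge = .initCross(config@dimSmall, config@dimLarge))),
    headSmall = list(W = .randMat(config@dimSmall, config@nClasses, 0.02),
                     b = rep(0, config@nClasses)),
    headLarge = list(W = .randMat(config@dimLarge, config@nClasses, 0.02),
                     b = rep(0, config@nClasses)))
  new("CrossViT", config = config, params = params)
}

# ---- primitive layers (plain matrices, tokens in rows) ---------------------

.linear <- function(X, W, b) sweep(X %*% W, 2, b, `+`)

.layerNorm <- function(X, g, b, eps = 1e-6) {
  m <- rowMeans(X)
  xc <- X - m
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  sweep(xc * inv, 2, g, `*`) + rep(b, each = nrow(X))
}

.softmaxRows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

.gelu <- function(x) x * stats::pnorm(x)

# multi-head self-attention on an (already normalized) token matrix
.msa <- function(Xn, p, heads) {
  Tn <- nrow(Xn); D <- ncol(Xn); dk <- D %/% heads
  Q <- .linear(Xn, p$Wq, p$bq)
  K <- .linear(Xn, p$Wk, p$bk)
  V <- .linear(Xn, p$Wv, p$bv)
  O <- matrix(0, Tn, D)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    A <- .softmaxRows(Q[, cols, drop = FALSE] %*%
                        t(K[, cols, drop = FALSE]) / sqrt(dk))
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  .linear(O, p$Wo, p$bo)
}

#' Embed image patches into a token sequence
#'
#' Splits the image into non-overlapping `patch x patch` squares (grid
#' row-major, channel values in R's column-major patch order, scaled to
#' `[0, 1]`), maps each flattened patch through a linear layer, prepends the
#' CLS token and adds the learned positional encoding to all `1 + N` slots.
#'
#' @param image an [RGBImage-class] with square size divisible by `patch`.
#' @param patch patch side length in px.
#' @param params branch parameter list with `embedW`, `embedB`, `cls`, `pos`.
#' @return `(1 + N) x dim` token matrix, CLS in row 1.
#' @export
embedPatches <- function(image, patch, params) {
  stopifnot(is(image, "RGBImage"))
  d <- dim(image)
  if (d[1] != d[2]) stop("backbone input must be square")
  if (d[1] %% patch != 0L)
    stop("image size ", d[1], " is not divisible by patch size ", patch)
  n <- d[1] %/% patch
  px <- image@.Data / 255
  P <- matrix(0, n * n, patch * patch * 3L)
  for (gy in seq_len(n)) for (gx in seq_len(n)) {
    rows <- ((gy - 1L) * patch + 1L):(gy * patch)
    cols <- ((gx - 1L) * patch + 1L):(gx * patch)
    P[(gy - 1L) * n + gx, ] <- as.numeric(px[rows, cols, ])
  }
  tok <- rbind(params$cls, .linear(P, params$embedW, params$embedB))
  tok + params$pos
}

#' One transformer encoder layer
#'
#' Pre-norm residual layer: `Y = X + MSA(LN(X))`, `out = Y + FFN(LN(Y))`,
#' with GELU activation inside the FFN. Shape preserving; every
#' self-attention row is a probability vector.
#'
#' @param x `(T x dim)` token matrix.
#' @param params an encoder layer parameter list (see [crossViT()]).
#' @param heads number of attention heads (must divide `dim`).
#' @return token matrix of the same shape.
#' @export
encoderLayer <- function(x, params, heads) {
  if (ncol(x) %% heads != 0L || ncol(x) != nrow(params$Wq))
    stop("token dimension does not match layer parameters/heads")
  y <- x + .msa(.layerNorm(x, params$ln1g, params$ln1b), params, heads)
  h <- .gelu(.linear(.layerNorm(y, params$ln2g, params$ln2b),
                     params$W1, params$b1))
  y + .linear(h, params$W2, params$b2)
}

#' Cross-attention CLS update
#'
#' Projects the destination branch's CLS token into the source branch's token
#' width, concatenates it with the source patch tokens, and lets the
#' projected CLS (as the sole query) attend over all `1 + N` positions
#' (scaled by `1/sqrt(d_k)`, keys/values from the layer-normalized
#' concatenation, value projection back to the CLS width). The attended value
#' is added residually to the original CLS.
#'
#' @param cls numeric CLS vector of the destination branch.
#' @param patches `N x dimPatch` matrix of source-branch patch tokens (may
#'   have zero rows).
#' @param params cross-attention parameter list (`Wf`, `bf`, `lng`, `lnb`,
#'   `Wq`, `bq`, `Wk`, `bk`, `Wv`, `bv`).
#' @param returnAttention also return the attention distribution.
#' @return the updated CLS vector, or (with `returnAttention`) a list
#'   `cls`, `attention`.
#' @export
crossAttentionFuse <- function(cls, patches, params, returnAttention = FALSE) {
  if (length(cls) != nrow(params$Wf))
    stop("CLS dimension does not match cross-attention projection")
  if (ncol(patches) > 0 && ncol(patches) != ncol(params$Wf))
    stop("patch token dimension does not match cross-attention projection")
  f <- .linear(matrix(cls, 1), params$Wf, params$bf)
  xp <- rbind(f, patches)
  xn <- .layerNorm(xp, params$lng, params$lnb)
  q <- .linear(xn[1, , drop = FALSE], params$Wq, params$bq)
  k <- .linear(xn, params$Wk, params$bk)
  v <- .linear(xn, params$Wv, params$bv)
  att <- .softmaxRows(q %*% t(k) / sqrt(ncol(k)))
  out <- cls + as.numeric(att %*% v)
  if (returnAttention) list(cls = out, attention = as.numeric(att)) else out
}

#' Run the backbone and extract per-branch CLS features
#'
#' Embeds both branches, runs their encoder stacks, applies the configured
#' number of bidirectional cross-attention rounds (both directions computed
#' from the pre-round state), and returns the final layer-normalized CLS
#' vectors. Deterministic: no dropout at inference.
#'
#' @param image an [RGBImage-class] of size `config@imageSize` (resize
#'   upstream).
#' @param model a [CrossViT-class].
#' @return a [DeepFeatures-class] with slots `small` and `large`.
#' @export
forwardFeatures <- function(image, model) {
  stopifnot(is(model, "CrossViT"))
  cfg <- model@config
  p <- model@params
  d <- dim(image)
  if (d[1] != cfg@imageSize || d[2] != cfg@imageSize)
    stop("image size ", d[1], "x", d[2], " does not match config imageSize ",
         cfg@imageSize)
  ts <- embedPatches(image, cfg@patchSmall, p$small)
  tl <- embedPatches(image, cfg@patchLarge, p$large)
  for (k in seq_len(cfg@depth)) {
    ts <- encoderLayer(ts, p$small$layers[[k]], cfg@heads)
    tl <- encoderLayer(tl, p$large$layers[[k]], cfg@heads)
  }
  for (r in seq_len(cfg@nCrossRounds)) {
    newL <- crossAttentionFuse(tl[1, ], ts[-1, , drop = FALSE],
                               p$cross[[r]]$largeFromSmall)
    newS <- crossAttentionFuse(ts[1, ], tl[-1, , drop = FALSE],
                               p$cross[[r]]$smallFromLarge)
    tl[1, ] <- newL
    ts[1, ] <- newS
  }
  zs <- as.numeric(.layerNorm(ts[1, , drop = FALSE], p$small$lnFg,
                              p$small$lnFb))
  zl <- as.numeric(.layerNorm(tl[1, , drop = FALSE], p$large$lnFg,
                              p$large$lnFb))
  new("DeepFeatures", small = zs, large = zl)
}

#' Fuse per-branch logits
#'
#' Applies the two linear classification heads to the branch CLS features and
#' averages them elementwise: `fused = (head_l(z_l) + head_s(z_s)) / 2`.
#'
#' @param features a [DeepFeatures-class].
#' @param headSmall,headLarge lists with `W` (dim x nClasses) and `b`.
#' @return list with `logitsSmall`, `logitsLarge`, `fused`.
#' @export
fuseLogits <- function(features, headSmall, headLarge) {
  stopifnot(is(features, "DeepFeatures"))
  if (length(features@small) != nrow(headSmall$W) ||
      length(features@large) != nrow(headLarge$W))
    stop("classification head dimensions do not match branch features")
  ls <- as.numeric(features@small %*% headSmall$W + headSmall$b)
  ll <- as.numeric(features@large %*% headLarge$W + headLarge$b)
  list(logitsSmall = ls, logitsLarge = ll, fused = (ls + ll) / 2)
}

#' Classify an image with the backbone alone
#'
#' @param image an [RGBImage-class] matching the model's input size.
#' @param model a [CrossViT-class].
#' @return list with `logitsSmall`, `logitsLarge`, `fused`, `prob`
#'   (softmax of fused) and `label` (argmax, ties to the lower class code).
#' @export
predictBackbone <- function(image, model) {
  feats <- forwardFeatures(image, model)
  lp <- fuseLogits(feats, model@params$headSmall, model@params$headLarge)
  e <- exp(lp$fused - max(lp$fused))
  prob <- e / sum(e)
  lp$prob <- prob
  lp$label <- which.max(prob)   # which.max takes the first (lower) on ties
  lp
}
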