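# Image I/O, grayscale conversion, the augmentation recipe, and dataset
# partitioning. File decoding/encoding is delegated to EBImage (PNG, TIFF,
# JPEG); everything here works on 8-bit H x W x 3 arrays.

#' Load an image file as an RGBImage
#'
#' Decodes PNG, TIFF or JPEG. Grayscale sources are replicated across the
#' three channels; an alpha channel is dropped. Pixel values are rescaled to
#' 8-bit integers.
#'
#' @param path file path.
#' @return an [RGBImage-class].
#' @export
loadImage <- function(path) {
  if (!file.exists(path))
    stop("cannot read image, file not found: ", path)
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e)
                    stop("cannot decode image file: ", path, " (",
                         conditionMessage(e), ")", call. = FALSE))
  a <- EBImage::imageData(img)   # x (col) by y (row) [by channel]
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
  nc <- dim(a)[3]
  if (nc == 1L) a <- a[, , c(1L, 1L, 1L), drop = FALSE]
  if (nc == 2L) a <- a[, , c(1L, 1L, 1L), drop = FALSE]   # gray + alpha
  if (nc >= 4L) a <- a[, , 1:3, drop = FALSE]
  px <- aperm(a, c(2L, 1L, 3L))                            # to H x W x 3
  RGBImage(round(pmin(pmax(px, 0), 1) * 255))
}

#' Write an RGBImage to disk
#'
#' Format is chosen from the file extension (`.png`, `.tif`/`.tiff`, `.jpg`/
#' `.jpeg`). PNG and TIFF round-trip 8-bit data bit-exactly.
#'
#' @param image an [RGBImage-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
saveImage <- function(image, path) {
  stopifnot(is(image, "RGBImage"))
  a <- aperm(image@.Data, c(2L, 1L, 3L)) / 255
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Convert an RGB image to grayscale
#'
#' Uses the conventional luminance weights 0.299/0.587/0.114 with
#' round-half-to-even to 8-bit integers; idempotent on already-gray input.
#'
#' @param image an [RGBImage-class].
#' @return an `H x W` matrix of integers in `[0, 255]`.
#' @export
toGrayscale <- function(image) {
  stopifnot(is(image, "RGBImage"))
  px <- image@.Data
  round(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
}

# inverse-map bilinear rotation about the image center with reflect padding;
# output cropped to the input size (shape preserving)
.rotateReflect <- function(px, angleDeg) {
  H <- dim(px)[1]; W <- dim(px)[2]
  th <- angleDeg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- rep(seq_len(H), times = W) - cy
  xx <- rep(seq_len(W), each = H) - cx
  # source coordinates = inverse rotation of the target grid
  sy <- cy + (-sin(-th)) * xx + cos(-th) * yy
  sx <- cx + cos(-th) * xx + sin(-th) * yy
  refl <- function(v, n) {
    v <- (v - 1) %% (2 * n - 2)
    ifelse(v > (n - 1), 2 * (n - 1) - v, v) + 1
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  y0r <- refl(y0, H); y1r <- refl(y0 + 1, H)
  x0r <- refl(x0, W); x1r <- refl(x0 + 1, W)
  out <- array(0, dim = dim(px))
  for (ch in 1:3) {
    m <- px[, , ch]
    v <- (1 - fy) * (1 - fx) * m[cbind(y0r, x0r)] +
         (1 - fy) * fx       * m[cbind(y0r, x1r)] +
         fy       * (1 - fx) * m[cbind(y1r, x0r)] +
         fy       * fx       * m[cbind(y1r, x1r)]
    out[, , ch] <- matrix(v, H, W)
  }
  out
}

#' Apply the augmentation recipe to an image
#'
#' Applies, in order: horizontal flip (with probability `hflipProb`), vertical
#' flip, rotation by an angle drawn uniformly from
#' `[-maxRotation, +maxRotation]` (bilinear resampling, reflect padding,
#' cropped back to the input size), then multiplicative brightness, contrast
#' (about mid-gray 128) and saturation jitter, each with a factor drawn
#' uniformly from `1 +/- delta`. Deterministic for a fixed `spec@seed`; a
#' zero-strength spec is the pixelwise identity.
#'
#' @param image an [RGBImage-class].
#' @param spec an [AugmentSpec-class].
#' @param returnParams also return the sampled transform parameters.
#' @return an [RGBImage-class] of the same dimensions, or (with
#'   `returnParams`) a list `image`, `params` where `params` records the
#'   applied flips, rotation angle and color factors.
#' @export
augmentImage <- function(image, spec, returnParams = FALSE) {
  stopifnot(is(image, "RGBImage"), is(spec, "AugmentSpec"))
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(spec@seed %% 2147483647L, kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  px <- image@.Data
  pars <- list(hflip = FALSE, vflip = FALSE, angle = 0,
               brightness = 1, contrast = 1, saturation = 1)
  if (spec@hflipProb > 0 && stats::runif(1) < spec@hflipProb) {
    px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
    pars$hflip <- TRUE
  }
  if (spec@vflipProb > 0 && stats::runif(1) < spec@vflipProb) {
    px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
    pars$vflip <- TRUE
  }
  if (spec@maxRotation > 0) {
    pars$angle <- stats::runif(1, -spec@maxRotation, spec@maxRotation)
    px <- .rotateReflect(px, pars$angle)
  }
  if (spec@brightnessDelta > 0) {
    pars$brightness <- stats::runif(1, 1 - spec@brightnessDelta,
                                    1 + spec@brightnessDelta)
    px <- px * pars$brightness
  }
  if (spec@contrastDelta > 0) {
    pars$contrast <- stats::runif(1, 1 - spec@contrastDelta,
                                  1 + spec@contrastDelta)
    px <- (px - 128) * pars$contrast + 128
  }
  if (spec@saturationDelta > 0) {
    pars$saturation <- stats::runif(1, 1 - spec@saturationDelta,
                                    1 + spec@saturationDelta)
    gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    for (ch in 1:3) px[, , ch] <- gray + pars$saturation * (px[, , ch] - gray)
  }
  out <- RGBImage(round(pmin(pmax(px, 0), 255)))
  if (returnParams) list(image = out, params = pars) else out
}

# floor-then-largest-remainder apportionment of n items to the given ratios;
# remainder ties broken by split order (train, val, test)
.splitSizes <- function(n, ratios) {
  tgt <- n * ratios
  base <- floor(tgt)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- tgt - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Partition a dataset into train / validation / test subsets
#'
#' Subset sizes follow the split ratios with a floor-then-largest-remainder
#' rounding rule (remainder ties broken in train, validation, test order), so
#' they always sum exactly to the dataset size. In stratified mode the rule is
#' applied within each class, keeping per-class shares within one item of the
#' targets. Items are shuffled with the spec's seed before assignment; the
#' three subsets are disjoint and cover the dataset.
#'
#' @param dataset a [HistoDataset-class].
#' @param spec a [SplitSpec-class].
#' @return named list of [HistoDataset-class]: `train`, `val`, `test`.
#' @examples
#' p <- histoPreset("easy")
#' ds <- generateDataset(p$class1, p$class2, 5, c(64, 64), seed = 1)
#' sp <- partitionDataset(ds, splitSpec(seed = 2))
#' vapply(sp, length, integer(1))
#' @export
partitionDataset <- function(dataset, spec) {
  stopifnot(is(dataset, "HistoDataset"), is(spec, "SplitSpec"))
  n <- length(dataset)
  if (n < 1L) stop("cannot partition an empty dataset")
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(spec@seed %% 2147483647L, kind = "Mersenne-Twister")
  assignGroup <- function(idx) {
    idx <- sample(idx)
    sz <- .splitSizes(length(idx), spec@ratios)
    list(train = idx[seq_len(sz[1])],
         val   = idx[sz[1] + seq_len(sz[2])],
         test  = idx[sz[1] + sz[2] + seq_len(sz[3])])
  }
  if (spec@stratify) {
    parts <- lapply(sort(unique(dataset@labels)), function(cl)
      assignGroup(which(dataset@labels == cl)))
    pick <- function(name) sort(unlist(lapply(parts, `[[`, name),
                                      use.names = FALSE))
  } else {
    parts <- assignGroup(seq_len(n))
    pick <- function(name) sort(parts[[name]])
  }
  list(train = dataset[pick("train")],
       val   = dataset[pick("val")],
       test  = dataset[pick("test")])
}

#' Mean circular hue of an image
#'
#' The circular mean (in degrees) of the per-pixel HSV hue. Useful for
#' checking that generated images carry the requested color statistics.
#'
#' @param image an [RGBImage-class].
#' @return hue in degrees, `[0, 360)`.
#' @export
meanCircularHue <- function(image) {
  stopifnot(is(image, "RGBImage"))
  px <- image@.Data
  hsv <- grDevices::rgb2hsv(as.numeric(px[, , 1]), as.numeric(px[, , 2]),
                            as.numeric(px[, , 3]), maxColorValue = 255)
  h <- hsv[1, ] * 2 * pi
  (atan2(mean(sin(h)), mean(cos(h))) * 180 / pi) %% 360
}
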