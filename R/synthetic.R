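# Synthetic H&E-like image generation.
#
# Images emulate hematoxylin/eosin contrast: a pink-ish eosin background whose
# brightness is modulated by a smooth multiplicative texture field, with
# purple hematoxylin-like nucleus blobs rendered as anti-aliased filled
# ellipses, plus per-channel Gaussian sensor noise. All randomness goes
# through R's Mersenne-Twister with inversion normals; the per-image seed
# derivation is documented in generateDataset().

# vectorized HSV (h in degrees, s,v in [0,1]) -> RGB in [0,1], n x 3 matrix
.hsv2rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# reflect-padded separable Gaussian smoothing of an H x W white-noise field,
# rescaled to zero mean / unit sd; sigma is the stated correlation length
.smoothField <- function(H, W, sigma) {
  z <- matrix(stats::rnorm(H * W), H, W)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  reflectIdx <- function(idx, n) {
    idx <- ((idx - 1) %% (2 * n))
    ifelse(idx < n, idx + 1, 2 * n - idx)
  }
  smooth1 <- function(m, along) {
    n <- if (along == 1) nrow(m) else ncol(m)
    out <- 0
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- reflectIdx(seq_len(n) + off, n)
      out <- out + k[j] * (if (along == 1) m[idx, , drop = FALSE]
                           else m[, idx, drop = FALSE])
    }
    out
  }
  z <- smooth1(smooth1(z, 1), 2)
  s <- stats::sd(as.numeric(z))
  if (s > 0) z <- z / s
  z - mean(z)
}

#' Generate one synthetic H&E-like image
#'
#' Renders an eosin-like background (hue/saturation from `appearance`, value
#' modulated by a multiplicative texture field of the stated correlation
#' length), draws `round(density * H * W / 1e4)` hematoxylin-like nucleus
#' blobs as anti-aliased filled ellipses with Gaussian-perturbed radii, and
#' adds per-channel Gaussian noise. Deterministic for a fixed
#' `(appearance, size, seed)` triple.
#'
#' @param appearance a [ClassAppearance-class].
#' @param size integer length-2 `(H, W)`, both at least 32.
#' @param seed integer seed.
#' @return an [RGBImage-class].
#' @examples
#' img <- generateImage(classAppearance(), c(64, 64), seed = 7)
#' @export
generateImage <- function(appearance, size = c(224L, 224L), seed = 1L) {
  stopifnot(is(appearance, "ClassAppearance"))
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 32L))
    stop("image size must be at least 32 x 32")
  H <- size[1]; W <- size[2]
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(as.integer(seed) %% 2147483647L, kind = "Mersenne-Twister",
           normal.kind = "Inversion")

  field <- 1 + 0.06 * .smoothField(H, W, appearance@textureGrain)
  vBg <- pmin(pmax(0.92 * field, 0), 1)
  bg <- .hsv2rgb(rep(appearance@backgroundHue, H * W),
                 rep(appearance@backgroundSat, H * W), as.numeric(vBg))

  nBlob <- round(appearance@nucleusDensity * H * W / 1e4)
  alphaMap <- matrix(0, H, W)
  if (nBlob >= 1) {
    for (b in seq_len(nBlob)) {
      cy <- stats::runif(1, 1, H)
      cx <- stats::runif(1, 1, W)
      rr <- max(1.2, stats::rnorm(1, appearance@nucleusRadius[1],
                                  appearance@nucleusRadius[2]))
      ecc <- stats::runif(1, 0.65, 1)
      th <- stats::runif(1, 0, pi)
      a <- rr / sqrt(ecc); bb <- rr * sqrt(ecc)
      ext <- ceiling(a) + 2L
      ys <- max(1L, floor(cy - ext)):min(H, ceiling(cy + ext))
      xs <- max(1L, floor(cx - ext)):min(W, ceiling(cx + ext))
      if (!length(ys) || !length(xs)) next
      dy <- ys - cy; dx <- xs - cx
      u <- outer(dy, dx, function(yy, xx) xx * cos(th) + yy * sin(th))
      v <- outer(dy, dx, function(yy, xx) -xx * sin(th) + yy * cos(th))
      d <- sqrt((u / a)^2 + (v / bb)^2)
      al <- pmin(pmax((1 - d) * rr, 0), 1)   # ~1 px anti-aliased edge
      alphaMap[ys, xs] <- pmax(alphaMap[ys, xs], al)
    }
  }
  vNuc <- pmin(pmax(0.35 * field, 0), 1)
  nuc <- .hsv2rgb(rep(appearance@nucleusHue, H * W), rep(0.55, H * W),
                  as.numeric(vNuc))
  A <- as.numeric(alphaMap)
  px <- (1 - A) * bg + A * nuc
  px <- px * 255 + matrix(stats::rnorm(H * W * 3, 0, appearance@jitterSd),
                          H * W, 3)
  px <- round(pmin(pmax(px, 0), 255))
  RGBImage(array(px, dim = c(H, W, 3)))
}

# documented per-image seed derivation: master seed plus a fixed odd stride
.imageSeed <- function(masterSeed, index) {
  (as.integer(masterSeed) %% 2147483647L +
     9973L * as.integer(index)) %% 2147483647L
}

#' Generate a balanced two-class synthetic dataset
#'
#' Produces exactly `2 * nPerClass` images: the first `nPerClass` drawn from
#' `class1` (label 1, normal-like), the rest from `class2` (label 2,
#' malignant-like). Image `i` (1-based, over the whole dataset) uses seed
#' `(seed + 9973 * i) mod (2^31 - 1)`, so the dataset is reproducible from
#' the master seed alone and any image can be regenerated in isolation.
#'
#' @param class1,class2 [ClassAppearance-class] objects for labels 1 and 2.
#' @param nPerClass images per class (>= 1).
#' @param size `(H, W)` in px.
#' @param seed master integer seed.
#' @param tag free-text tag stored per image (e.g. emulated magnification).
#' @return a [HistoDataset-class].
#' @examples
#' p <- histoPreset("easy")
#' ds <- generateDataset(p$class1, p$class2, nPerClass = 2, size = c(64, 64),
#'                       seed = 1)
#' length(ds)
#' @export
generateDataset <- function(class1, class2, nPerClass, size = c(224L, 224L),
                            seed = 1L, tag = "synthetic") {
  if (!is.numeric(nPerClass) || nPerClass < 1)
    stop("nPerClass must be >= 1")
  nPerClass <- as.integer(nPerClass)
  apps <- c(rep(list(class1), nPerClass), rep(list(class2), nPerClass))
  labels <- rep(c(1L, 2L), each = nPerClass)
  imgs <- lapply(seq_along(apps), function(i)
    generateImage(apps[[i]], size, .imageSeed(seed, i)))
  HistoDataset(imgs, labels, rep(tag, length(imgs)))
}

#' Bundled synthetic class-appearance presets
#'
#' `"easy"`: the two classes differ by a 40-degree background hue gap,
#' clearly distinct texture correlation lengths and nucleus densities --
#' separable by color alone. `"hard"`: an 8-degree hue gap, overlapping
#' texture parameters and stronger noise.
#'
#' @param name `"easy"` or `"hard"`.
#' @return list with elements `class1` (normal-like) and `class2`
#'   (malignant-like), both [ClassAppearance-class].
#' @export
histoPreset <- function(name = c("easy", "hard")) {
  name <- match.arg(name)
  if (name == "easy") {
    list(
      class1 = classAppearance(backgroundHue = 330, backgroundSat = 0.25,
                               nucleusHue = 270, nucleusDensity = 25,
                               nucleusRadius = c(3, 0.8), textureGrain = 6,
                               jitterSd = 3),
      class2 = classAppearance(backgroundHue = 290, backgroundSat = 0.25,
                               nucleusHue = 265, nucleusDensity = 55,
                               nucleusRadius = c(4, 1), textureGrain = 2,
                               jitterSd = 3)
    )
  } else {
    list(
      class1 = classAppearance(backgroundHue = 330, backgroundSat = 0.25,
                               nucleusHue = 270, nucleusDensity = 25,
                               nucleusRadius = c(3, 0.8), textureGrain = 6,
                               jitterSd = 6),
      class2 = classAppearance(backgroundHue = 322, backgroundSat = 0.25,
                               nucleusHue = 268, nucleusDensity = 32,
                               nucleusRadius = c(3.2, 0.9), textureGrain = 5,
                               jitterSd = 6)
    )
  }
}

#' Write a dataset to disk as PNG files plus a manifest
#'
#' Writes `img_0001.png`, ... into `dir` and a `manifest.csv` with columns
#' `path`, `label`, `tag` (paths relative to the manifest location).
#'
#' @param dataset a [HistoDataset-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data.frame.
#' @export
writeDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "HistoDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset)
  paths <- sprintf("img_%04d.png", seq_len(n))
  for (i in seq_len(n))
    saveImage(dataset@images[[i]], file.path(dir, paths[i]))
  manifest <- data.frame(path = paths, label = dataset@labels,
                         tag = dataset@tags, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a manifest CSV and load the images it lists
#'
#' @param manifestPath path to a `manifest.csv` with columns `path`, `label`,
#'   `tag`; image paths are resolved relative to the manifest's directory.
#' @return a [HistoDataset-class].
#' @export
readDataset <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stop("manifest not found: ", manifestPath)
  manifest <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("path", "label", "tag")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns path, label, tag")
  base <- dirname(manifestPath)
  imgs <- lapply(manifest$path, function(p) loadImage(file.path(base, p)))
  HistoDataset(imgs, manifest$label, manifest$tag)
}
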