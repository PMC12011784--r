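# Gray-level co-occurrence matrix (GLCM) texture statistics.
#
# The grayscale image is quantized to G = 64 levels (floor(gray / 4)).
# Symmetric, normalized co-occurrence matrices are built at distance 1 for
# the four standard angles; from each matrix six statistics are computed, for
# 6 x 4 = 24 values. Feature order is angle-major: for each angle (0, 45, 90,
# 135 degrees, in that order) the statistics contrast, dissimilarity,
# homogeneity, energy, correlation, entropy.

# (row, col) displacement per angle; rows grow downward so 45 deg looks
# up-and-right
.glcmOffsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
                     `135` = c(-1L, -1L))

# symmetric normalized co-occurrence matrix of a quantized (0-based) level
# matrix at one displacement
.glcmMatrix <- function(q, offset, G = 64L) {
  H <- nrow(q); W <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1L, 1L - dr):min(H, H - dr)
  c1 <- max(1L, 1L - dc):min(W, W - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  idx <- as.numeric(a) * G + as.numeric(b) + 1
  counts <- tabulate(idx, nbins = G * G)
  m <- matrix(counts, G, G, byrow = TRUE)
  m <- m + t(m)
  m / sum(m)
}

# the six statistics of one normalized GLCM, in documented order
.glcmStats <- function(p, G = 64L) {
  lev <- 0:(G - 1L)
  i <- matrix(lev, G, G)
  j <- t(i)
  d <- i - j
  contrast <- sum(p * d^2)
  dissimilarity <- sum(p * abs(d))
  homogeneity <- sum(p / (1 + d^2))
  energy <- sum(p^2)
  pi_ <- rowSums(p)
  mu <- sum(lev * pi_)
  sig <- sqrt(sum((lev - mu)^2 * pi_))
  correlation <- if (sig > 0) sum((i - mu) * (j - mu) * p) / sig^2 else 0
  nz <- p[p > 0]
  entropy <- -sum(nz * log(nz))
  c(contrast = contrast, dissimilarity = dissimilarity,
    homogeneity = homogeneity, energy = energy, correlation = correlation,
    entropy = entropy)
}

#' Gray-level co-occurrence matrix features (24 values)
#'
#' Quantizes the grayscale image to 64 levels and builds symmetric normalized
#' co-occurrence matrices at distance 1 for angles 0, 45, 90 and 135 degrees.
#' For each angle it reports contrast, dissimilarity, homogeneity, energy,
#' correlation and entropy (natural log, with `0 * log 0 = 0`; correlation is
#' 0 when either marginal standard deviation is 0).
#'
#' @param image an [RGBImage-class] with at least 2 px in each dimension.
#' @return numeric vector of length 24 (names `glcm_00` ... `glcm_23`),
#'   angle-major order.
#' @export
glcmFeatures <- function(image) {
  stopifnot(is(image, "RGBImage"))
  g <- toGrayscale(image)
  if (nrow(g) < 2L || ncol(g) < 2L)
    stop("image must be at least 2 px in each dimension")
  q <- matrix(pmin(floor(g / 4), 63), nrow(g), ncol(g))
  out <- unlist(lapply(.glcmOffsets, function(off)
    .glcmStats(.glcmMatrix(q, off))), use.names = FALSE)
  names(out) <- sprintf("glcm_%02d", 0:23)
  out
}
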