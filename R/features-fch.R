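# Fuzzy color histogram (FCH).
#
# 768 bins = 12 hue x 8 saturation x 8 value over HSV. Each dimension carries
# triangular membership functions peaking at the bin centers and falling
# linearly to zero at the neighboring centers (a partition of unity), with
# circular wrap on hue and mass clamped to the edge bins on saturation/value.
# Every pixel therefore distributes exactly unit mass over at most 2x2x2 = 8
# bins; the histogram is normalized by pixel count and sums to 1.

# triangular memberships along one linear dimension with nb bins on [0, 1];
# centers at (k - 0.5) / nb; returns lower bin (1-based), upper bin, and the
# fraction of mass assigned to the upper bin
.triLinear <- function(x, nb) {
  t <- x * nb - 0.5
  t <- pmin(pmax(t, 0), nb - 1)        # clamp: edge bins absorb the tails
  lo <- floor(t)
  frac <- t - lo
  list(lo = as.integer(lo) + 1L, hi = pmin(as.integer(lo) + 2L, nb),
       frac = frac)
}

# circular version for hue (x in degrees)
.triCircular <- function(x, nb) {
  t <- (x / 360) * nb - 0.5
  lo <- floor(t)
  frac <- t - lo
  list(lo = (as.integer(lo) %% nb) + 1L,
       hi = ((as.integer(lo) + 1L) %% nb) + 1L,
       frac = frac)
}

.pixelHSV <- function(image) {
  px <- image@.Data
  hsv <- grDevices::rgb2hsv(as.numeric(px[, , 1]), as.numeric(px[, , 2]),
                            as.numeric(px[, , 3]), maxColorValue = 255)
  list(h = hsv[1, ] * 360, s = hsv[2, ], v = hsv[3, ])
}

.accumBins <- function(idx, w, nbins) {
  out <- numeric(nbins)
  s <- tapply(w, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

#' Fuzzy color histogram features (768 values)
#'
#' Computes a 768-bin fuzzy color histogram over HSV (12 hue x 8 saturation x
#' 8 value bins). Triangular membership functions let each pixel spread its
#' unit mass over the neighboring bins in each dimension, which makes the
#' histogram robust to small color shifts such as staining variation. The
#' result is normalized by pixel count and sums to 1.
#'
#' Bin layout: index `((h-1) * 8 + (s-1)) * 8 + v` for hue bin `h`,
#' saturation bin `s`, value bin `v` (all 1-based).
#'
#' @param image an [RGBImage-class].
#' @return numeric vector of length 768 (names `fch_000` ... `fch_767`),
#'   non-negative, summing to 1.
#' @export
fchFeatures <- function(image) {
  stopifnot(is(image, "RGBImage"))
  hsv <- .pixelHSV(image)
  hb <- .triCircular(hsv$h, 12L)
  sb <- .triLinear(hsv$s, 8L)
  vb <- .triLinear(hsv$v, 8L)
  n <- length(hsv$h)
  acc <- numeric(768)
  for (ih in 1:2) for (is in 1:2) for (iv in 1:2) {
    hIdx <- if (ih == 1) hb$lo else hb$hi
    sIdx <- if (is == 1) sb$lo else sb$hi
    vIdx <- if (iv == 1) vb$lo else vb$hi
    w <- (if (ih == 1) 1 - hb$frac else hb$frac) *
         (if (is == 1) 1 - sb$frac else sb$frac) *
         (if (iv == 1) 1 - vb$frac else vb$frac)
    keep <- w > 0
    if (any(keep)) {
      idx <- ((hIdx[keep] - 1L) * 8L + (sIdx[keep] - 1L)) * 8L + vIdx[keep]
      acc <- acc + .accumBins(idx, w[keep], 768L)
    }
  }
  out <- acc / n
  names(out) <- sprintf("fch_%03d", 0:767)
  out
}

# crisp (hard-binned) 768-bin HSV histogram over the same bin grid; used as
# the non-fuzzy reference when assessing robustness to small color shifts
.crispColorHistogram <- function(image) {
  hsv <- .pixelHSV(image)
  hIdx <- pmin(floor(hsv$h / 30), 11) + 1L
  sIdx <- pmin(floor(hsv$s * 8), 7) + 1L
  vIdx <- pmin(floor(hsv$v * 8), 7) + 1L
  idx <- ((hIdx - 1L) * 8L + (sIdx - 1L)) * 8L + vIdx
  tabulate(idx, nbins = 768L) / length(idx)
}
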