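# Rotation-invariant uniform local binary patterns.
#
# P = 24 circular neighbors at radius R = 3, neighbor values by bilinear
# interpolation, comparator "neighbor >= center". Uniform codes (at most two
# 0/1 transitions around the circle) are mapped to their number of set bits
# (0..24); all non-uniform codes share one catch-all bin, giving P + 2 = 26
# histogram bins. The histogram is computed over interior pixels (margin R)
# and normalized to sum to 1.

.lbpOffsets <- function(P = 24L, R = 3) {
  a <- 2 * pi * (seq_len(P) - 1L) / P
  # snap away 1e-16 trigonometric noise so cardinal neighbors are exact and
  # the neighbor set maps onto itself under 90-degree image rotation
  list(dx = round(R * cos(a), 8), dy = round(-R * sin(a), 8))
}

#' Local binary pattern features (26 values)
#'
#' Histogram of rotation-invariant uniform LBP codes with 24 circular
#' neighbors at radius 3 on the grayscale image. Each interior pixel is
#' compared against its bilinearly interpolated neighbors
#' (`neighbor >= center`); uniform patterns are binned by their count of set
#' bits and non-uniform patterns share a final catch-all bin (26 bins total).
#'
#' @param image an [RGBImage-class], at least 7 px in each dimension.
#' @return numeric vector of length 26 (names `lbp_00` ... `lbp_25`),
#'   non-negative, summing to 1.
#' @export
lbpFeatures <- function(image) {
  stopifnot(is(image, "RGBImage"))
  P <- 24L; R <- 3L
  g <- toGrayscale(image)
  H <- nrow(g); W <- ncol(g)
  if (H < 2L * R + 1L || W < 2L * R + 1L)
    stop("image must be at least ", 2 * R + 1, " px in each dimension")
  off <- .lbpOffsets(P, R)
  rows <- (R + 1L):(H - R)
  cols <- (R + 1L):(W - R)
  center <- g[rows, cols, drop = FALSE]
  nInt <- length(center)
  bits <- matrix(FALSE, nInt, P)
  for (p in seq_len(P)) {
    dy <- off$dy[p]; dx <- off$dx[p]
    y0 <- floor(dy); x0 <- floor(dx)
    fy <- dy - y0; fx <- dx - x0
    sub <- function(oy, ox) g[rows + oy, cols + ox, drop = FALSE]
    smp <- (1 - fy) * (1 - fx) * sub(y0, x0)
    if (fx > 0) smp <- smp + (1 - fy) * fx * sub(y0, x0 + 1L)
    if (fy > 0) smp <- smp + fy * (1 - fx) * sub(y0 + 1L, x0)
    if (fy > 0 && fx > 0) smp <- smp + fy * fx * sub(y0 + 1L, x0 + 1L)
    # comparator "neighbor >= center"; the 1e-7 slack only absorbs
    # floating-point noise from interpolating integer-valued pixels
    bits[, p] <- as.numeric(smp) - as.numeric(center) >= -1e-7
  }
  transitions <- rowSums(bits != bits[, c(2:P, 1L), drop = FALSE])
  nset <- rowSums(bits)
  bin <- ifelse(transitions <= 2L, nset + 1L, P + 2L)   # 1..26
  out <- tabulate(bin, nbins = P + 2L) / nInt
  names(out) <- sprintf("lbp_%02d", 0:(P + 1L))
  out
}
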