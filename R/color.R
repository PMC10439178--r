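# Color-space conversions used throughout the pipeline. All conversions are
# vectorized over pixels; inputs are 8-bit sRGB in [0, 255] unless noted.

# sRGB (D65) -> linear RGB, IEC 61966-2-1
.srgb_decode <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

.srgb_encode <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

# Linear RGB <-> XYZ matrices (sRGB primaries, D65 white)
.M_RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)
.M_XYZ2RGB <- solve(.M_RGB2XYZ)
.WHITE_D65 <- c(X = 0.95047, Y = 1.0, Z = 1.08883)

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' Convert 8-bit sRGB to CIELAB
#'
#' Standard sRGB (IEC 61966-2-1) to CIELAB conversion under the D65 white
#' point and the 2 degree observer.
#'
#' @param rgb An n x 3 matrix of sRGB values in \[0, 255\], or an H x W x 3
#'   array (returned in the same shape).
#' @return Matching structure of CIELAB values (L in \[0, 100\]).
#' @export
srgb_to_lab <- function(rgb) {
  arr <- NULL
  if (is.array(rgb) && length(dim(rgb)) == 3) {
    arr <- dim(rgb)
    rgb <- matrix(rgb, ncol = 3)
  }
  if (!is.matrix(rgb) || ncol(rgb) != 3) {
    stop("rgb must be an n x 3 matrix or H x W x 3 array")
  }
  lin <- .srgb_decode(rgb / 255)
  xyz <- lin %*% t(.M_RGB2XYZ)
  fx <- .lab_f(xyz[, 1] / .WHITE_D65[1])
  fy <- .lab_f(xyz[, 2] / .WHITE_D65[2])
  fz <- .lab_f(xyz[, 3] / .WHITE_D65[3])
  lab <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (!is.null(arr)) {
    lab <- array(lab, dim = arr)
  }
  lab
}

#' Convert CIELAB to 8-bit sRGB
#'
#' Inverse of [srgb_to_lab()]; out-of-gamut values are clipped to \[0, 255\].
#'
#' @param lab n x 3 matrix of CIELAB values (or H x W x 3 array).
#' @return Matching structure of sRGB values in \[0, 255\] (not rounded).
#' @export
lab_to_srgb <- function(lab) {
  arr <- NULL
  if (is.array(lab) && length(dim(lab)) == 3) {
    arr <- dim(lab)
    lab <- matrix(lab, ncol = 3)
  }
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  xyz <- cbind(
    .lab_finv(fx) * .WHITE_D65[1],
    .lab_finv(fy) * .WHITE_D65[2],
    .lab_finv(fz) * .WHITE_D65[3]
  )
  lin <- xyz %*% t(.M_XYZ2RGB)
  rgb <- 255 * .srgb_encode(pmin(pmax(lin, 0), 1))
  rgb <- pmin(pmax(rgb, 0), 255)
  if (!is.null(arr)) {
    rgb <- array(rgb, dim = arr)
  }
  rgb
}

#' Convert 8-bit sRGB to HSV
#'
#' @param rgb n x 3 matrix or H x W x 3 array, values in \[0, 255\].
#' @return Matching structure with H in degrees \[0, 360), S and V in \[0, 1\].
#' @export
srgb_to_hsv <- function(rgb) {
  arr <- NULL
  if (is.array(rgb) && length(dim(rgb)) == 3) {
    arr <- dim(rgb)
    rgb <- matrix(rgb, ncol = 3)
  }
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 255))
  hsv[, 1] <- hsv[, 1] * 360
  colnames(hsv) <- c("h", "s", "v")
  if (!is.null(arr)) {
    hsv <- array(hsv, dim = arr)
  }
  hsv
}

#' Convert 8-bit sRGB to YCbCr
#'
#' Full-range BT.601 (JPEG) convention: Y, Cb, Cr all in \[0, 255\] with
#' chroma centered on 128.
#'
#' @param rgb n x 3 matrix or H x W x 3 array, values in \[0, 255\].
#' @return Matching structure of Y, Cb, Cr values.
#' @export
srgb_to_ycbcr <- function(rgb) {
  arr <- NULL
  if (is.array(rgb) && length(dim(rgb)) == 3) {
    arr <- dim(rgb)
    rgb <- matrix(rgb, ncol = 3)
  }
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  ycc <- cbind(
    y  = 0.299 * r + 0.587 * g + 0.114 * b,
    cb = 128 - 0.168736 * r - 0.331264 * g + 0.5 * b,
    cr = 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  )
  if (!is.null(arr)) {
    ycc <- array(ycc, dim = arr)
  }
  ycc
}

#' Individual typology angle (ITA) from CIELAB
#'
#' ITA = arctan((L - 50) / b) * 180 / pi, in degrees. Higher values indicate
#' lighter skin. Degenerate chroma (b = 0) maps to +/-90 degrees by the sign
#' of (L - 50), and to 0 when additionally L = 50, so the result always lies
#' in (-90, 90\].
#'
#' @param L CIELAB L* values.
#' @param b CIELAB b* values (same length).
#' @return ITA in degrees, in (-90, 90\].
#' @export
ita_angle <- function(L, b) {
  out <- atan((L - 50) / b) * 180 / pi
  deg <- b == 0
  out[deg] <- sign(L[deg] - 50) * 90
  out[deg & L == 50] <- 0
  out
}
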