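# sRGB <-> CIELAB conversions under D65 (2-degree observer), relative
# luminance, and gamut handling. All color math is floating point; colors are
# n x 3 matrices (or length-3 vectors) with sRGB channels in [0, 1] and
# CIELAB columns L, a, b.

# IEC 61966-2-1 linear-RGB -> XYZ matrix, D65. Row sums give the white point,
# so (1,1,1) maps to L* = 100 with |a*|,|b*| below 1e-3.
.RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.XYZ2RGB <- solve(.RGB2XYZ)
.WHITE <- rowSums(.RGB2XYZ) # D65 white (X_n, Y_n, Z_n)

.as_color_matrix <- function(x, what = "color") {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop(what, " must have 3 components", call. = FALSE)
    x <- matrix(as.numeric(x), nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L) stop(what, " must have 3 columns", call. = FALSE)
    storage.mode(x) <- "double"
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  x
}

.srgb_decode <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

.srgb_encode <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' Convert encoded sRGB to CIELAB
#'
#' Applies the standard sRGB piecewise decoding, the D65 linear-RGB to XYZ
#' matrix, and the CIE L*a*b* transform (cube-root with linear segment near
#' black). All perceptual-contrast computations in this package happen in the
#' resulting space.
#'
#' @param x a length-3 vector or n x 3 matrix of sRGB channels in `[0, 1]`.
#' @return an n x 3 matrix with columns `L`, `a`, `b` (a vector input yields
#'   a 1 x 3 matrix).
#' @export
#' @examples
#' srgb_to_lab(c(1, 1, 1)) # reference white, L* = 100
srgb_to_lab <- function(x) {
  x <- .as_color_matrix(x, "sRGB color")
  if (any(x < 0 | x > 1)) {
    stop("sRGB channels must lie in [0, 1]", call. = FALSE)
  }
  xyz <- .srgb_decode(x) %*% t(.RGB2XYZ)
  f <- .lab_f(sweep(xyz, 2L, .WHITE, "/"))
  out <- cbind(L = 116 * f[, 2L] - 16,
               a = 500 * (f[, 1L] - f[, 2L]),
               b = 200 * (f[, 2L] - f[, 3L]))
  out
}

#' Convert CIELAB to encoded sRGB, with gamut mapping
#'
#' Exact inverse of [srgb_to_lab()] for in-gamut colors. Out-of-gamut inputs
#' are clipped channel-wise in linear RGB and flagged via the
#' `"out_of_gamut"` attribute (a logical vector, one element per color), so
#' callers such as the colormap builder can reject paths that leave the
#' display gamut.
#'
#' @param x a length-3 vector or n x 3 matrix with columns L, a, b.
#' @param tol numeric excursions up to `tol` (linear-RGB units) are treated
#'   as numerical noise, not flagged.
#' @return an n x 3 sRGB matrix in `[0, 1]` with attribute `out_of_gamut`.
#' @export
lab_to_srgb <- function(x, tol = 1e-7) {
  x <- .as_color_matrix(x, "Lab color")
  fy <- (x[, 1L] + 16) / 116
  f <- cbind(fy + x[, 2L] / 500, fy, fy - x[, 3L] / 200)
  xyz <- sweep(.lab_finv(f), 2L, .WHITE, "*")
  lin <- xyz %*% t(.XYZ2RGB)
  oog <- apply(lin < -tol | lin > 1 + tol, 1L, any)
  lin[lin < 0] <- 0
  lin[lin > 1] <- 1
  out <- .srgb_encode(lin)
  dimnames(out) <- list(NULL, c("r", "g", "b"))
  attr(out, "out_of_gamut") <- oog
  out
}

#' Relative luminance of an sRGB color
#'
#' The Y component of the D65 XYZ representation: 0 for black, 1 for
#' reference white. Used by the auditor to test luminance monotonicity,
#' the property that makes a colormap readable for viewers with any
#' color-vision deficiency.
#'
#' @param x a length-3 vector or n x 3 matrix of sRGB channels in `[0, 1]`.
#' @return numeric vector of luminances in `[0, 1]`.
#' @export
relative_luminance <- function(x) {
  x <- .as_color_matrix(x, "sRGB color")
  if (any(x < 0 | x > 1)) {
    stop("sRGB channels must lie in [0, 1]", call. = FALSE)
  }
  as.numeric(.srgb_decode(x) %*% .RGB2XYZ[2L, ])
}

#' Quantize sRGB floats to 8-bit integers
#'
#' Half-up rounding to 0..255; idempotent on already-quantized values.
#' Internal color math stays floating point, quantization happens only at
#' export.
#'
#' @param x sRGB channels in `[0, 1]`.
#' @return integer values in 0..255 with the shape of `x`.
#' @export
srgb_to_8bit <- function(x) {
  if (any(x < 0 | x > 1)) stop("sRGB channels must lie in [0, 1]", call. = FALSE)
  storage.mode(x) <- "double"
  out <- floor(x * 255 + 0.5)
  storage.mode(out) <- "integer"
  out
}
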