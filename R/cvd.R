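# Color-vision-deficiency simulation. Dichromacy (deuteranopia, protanopia,
# tritanopia) uses the Machado et al. severity-parameterized matrices as
# shipped by the colorspace package, applied in *linear* RGB so the
# physiological model operates on light, not on gamma-encoded code values.
# Achromatopsia (no Machado matrix exists) is projection onto the neutral
# axis at equal relative luminance.

.CVD_KINDS <- c("deuteranopia", "protanopia", "tritanopia", "achromatopsia")

.machado_matrix <- function(kind, severity) {
  tabs <- switch(kind,
    deuteranopia = colorspace::deutanomaly_cvd,
    protanopia   = colorspace::protanomaly_cvd,
    tritanopia   = colorspace::tritanomaly_cvd)
  s <- 10 * severity
  i <- floor(s)
  frac <- s - i
  m <- tabs[[as.character(i)]]
  if (frac > 0) m <- (1 - frac) * m + frac * tabs[[as.character(i + 1)]]
  m
}

#' Simulate color-vision deficiency
#'
#' Physiologically based simulation of how a colormap appears to viewers
#' with a color-vision deficiency. For the three dichromacies the Machado
#' severity matrices (interpolated at 0.1 steps) act on linear RGB; severity
#' interpolates between identity (0) and the full deficiency (1).
#' Achromatopsia maps each color toward the gray of equal relative
#' luminance.
#'
#' @param x a length-3 vector or n x 3 matrix of sRGB channels in `[0, 1]`.
#' @param kind one of `"deuteranopia"`, `"protanopia"`, `"tritanopia"`,
#'   `"achromatopsia"`.
#' @param severity fraction in `[0, 1]`; 0 returns the input unchanged.
#' @return an n x 3 sRGB matrix in `[0, 1]`.
#' @export
simulate_cvd <- function(x, kind, severity = 1) {
  kind <- match.arg(kind, .CVD_KINDS)
  if (!is.numeric(severity) || length(severity) != 1L ||
      severity < 0 || severity > 1) {
    stop("severity must be a single number in [0, 1]", call. = FALSE)
  }
  x <- .as_color_matrix(x, "sRGB color")
  if (any(x < 0 | x > 1)) {
    stop("sRGB channels must lie in [0, 1]", call. = FALSE)
  }
  if (severity == 0) return(x)
  lin <- .srgb_decode(x)
  if (kind == "achromatopsia") {
    y <- as.numeric(lin %*% .RGB2XYZ[2L, ])
    gray <- matrix(y, nrow = nrow(lin), ncol = 3L)
    out <- (1 - severity) * lin + severity * gray
  } else {
    out <- lin %*% t(.machado_matrix(kind, severity))
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  res <- .srgb_encode(out)
  dimnames(res) <- list(NULL, c("r", "g", "b"))
  res
}
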