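# The central artifact: an ordered sequence of display colors (256 for the
# recommended maps) plus metadata. Entries are kept as floating-point sRGB;
# 8-bit quantization happens only on export.

#' Create a colormap object
#'
#' @param entries an n x 3 matrix of sRGB channels in `[0, 1]`; entry 1 is
#'   the "low" end of the display range.
#' @param name label used in file output and provenance records.
#' @param inverted logical; `TRUE` if the entry order has been reversed
#'   relative to the original orientation.
#' @param source `"built"` for maps produced by [build_colormap()],
#'   `"loaded"` for maps read from a table.
#' @param build optional list of build diagnostics (iterations, achieved CV,
#'   convergence flag).
#' @return an object of class `relax_cmap`.
#' @export
colormap <- function(entries, name = "unnamed", inverted = FALSE,
                     source = c("built", "loaded"), build = NULL) {
  entries <- .as_color_matrix(entries, "colormap entries")
  if (any(entries < 0 | entries > 1)) {
    stop("colormap entries must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(entries) < 2L) stop("a colormap needs at least 2 entries", call. = FALSE)
  dimnames(entries) <- list(NULL, c("r", "g", "b"))
  structure(list(entries = entries, name = name, inverted = isTRUE(inverted),
                 source = match.arg(source), build = build),
            class = "relax_cmap")
}

#' @export
print.relax_cmap <- function(x, ...) {
  cat(sprintf("<relax_cmap> %s: %d entries, %s%s\n", x$name,
              nrow(x$entries), x$source,
              if (x$inverted) ", inverted" else ""))
  if (!is.null(x$build)) {
    cat(sprintf("  equalized: CV = %.4g after %d iteration(s)%s\n",
                x$build$cv, x$build$iterations,
                if (isTRUE(x$build$converged)) "" else " [NOT CONVERGED]"))
  }
  invisible(x)
}

#' @export
length.relax_cmap <- function(x) nrow(x$entries)

#' Reverse a colormap's orientation
#'
#' Reverses the entry order only and toggles the `inverted` flag. Both
#' orientations of the recommended maps are legitimate displays; rate maps
#' (R1, R2) conventionally use the inverted time-map so that, combined with
#' logarithmic scaling, a rate map looks like its reciprocal time map.
#'
#' @param cmap a `relax_cmap`.
#' @return the reversed colormap; applying twice restores the original.
#' @export
invert_colormap <- function(cmap) {
  stopifnot(inherits(cmap, "relax_cmap"))
  cmap$entries <- cmap$entries[rev(seq_len(nrow(cmap$entries))), , drop = FALSE]
  cmap$inverted <- !cmap$inverted
  cmap$name <- if (endsWith(cmap$name, "-inv")) {
    substr(cmap$name, 1L, nchar(cmap$name) - 4L)
  } else {
    paste0(cmap$name, "-inv")
  }
  cmap
}

#' Grayscale reference colormap
#'
#' Black-to-white ramp with equal steps in *encoded* sRGB — the
#' conventional grayscale display that perceptually linearized maps are
#' compared against (its mean successive CIEDE2000 step is about 0.29 at
#' 256 levels, versus about 0.44 for the recommended maps).
#'
#' @param n number of entries.
#' @return a `relax_cmap`.
#' @export
grayscale_colormap <- function(n = 256) {
  g <- seq(0, 1, length.out = n)
  colormap(cbind(g, g, g), name = "grayscale", source = "built")
}

#' Jet-style rainbow colormap (audit fixture)
#'
#' The classic blue-cyan-yellow-red rainbow, reproduced here because it is
#' the canonical example of a map that fails the luminance-monotonicity
#' audit (its brightest color sits mid-range). The builder refuses such
#' anchor sets; the auditor accepts and flags them.
#'
#' @param n number of entries.
#' @return a `relax_cmap`.
#' @export
jet_colormap <- function(n = 256) {
  u <- seq(0, 1, length.out = n)
  ramp <- function(x) pmin(pmax(x, 0), 1)
  r <- ramp(1.5 - abs(4 * u - 3))
  g <- ramp(1.5 - abs(4 * u - 2))
  b <- ramp(1.5 - abs(4 * u - 1))
  colormap(cbind(r, g, b), name = "jet-like", source = "built")
}
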