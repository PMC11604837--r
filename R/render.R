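# Rendering: quantitative map + colormap + display window -> raster image,
# plus the mandatory color bar with readable numbers and units. Display
# rules: the sentinel (0/NaN) always renders exactly black; valid values
# below the window clamp to the first colormap entry (which, for built
# maps, is never black); values above clamp to the last entry.

#' @export
print.rendered_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rendered_image> %d x %d px", d[1L], d[2L]))
  p <- x$provenance
  if (!is.null(p$colormap)) {
    cat(sprintf(" | %s, %g..%g %s (%s), kind %s", p$colormap,
                p$vmin, p$vmax, p$units, p$scale,
                if (is.null(p$kind)) "?" else p$kind))
  }
  cat("\n")
  invisible(x)
}

.new_image <- function(pixels, provenance = list()) {
  structure(list(pixels = pixels, provenance = provenance),
            class = "rendered_image")
}

#' Render a quantitative map to colors
#'
#' Valid pixels are mapped through [value_to_position()] and
#' [position_to_entry()]; every sentinel pixel (0 or NaN) becomes exactly
#' black, the reserved invalidity color. The source values are never
#' transformed: logarithmic display only reparameterizes the colormap
#' lookup.
#'
#' @param qmap a [quant_map()].
#' @param cmap a `relax_cmap`.
#' @param range a [value_range()]; units must agree with the map's.
#' @return a `rendered_image` with provenance (colormap, window, scale,
#'   kind) recorded.
#' @export
render_map <- function(qmap, cmap, range) {
  stopifnot(inherits(qmap, "quant_map"), inherits(cmap, "relax_cmap"),
            inherits(range, "value_range"))
  if (qmap$units != range$units) {
    stop(sprintf("unit mismatch: map in '%s', range in '%s'",
                 qmap$units, range$units), call. = FALSE)
  }
  v <- qmap$values
  if (any(is.finite(v) & v < 0)) stop("negative relaxation values", call. = FALSE)
  valid <- is.finite(v) & v > 0
  h <- nrow(v); w <- ncol(v)
  pixels <- array(0, dim = c(h, w, 3L))
  if (any(valid)) {
    idx <- position_to_entry(value_to_position(v[valid], range),
                             nrow(cmap$entries)) + 1L
    cols <- cmap$entries[idx, , drop = FALSE]
    for (ch in 1:3) {
      plane <- matrix(0, h, w)
      plane[valid] <- cols[, ch]
      pixels[, , ch] <- plane
    }
  }
  .new_image(pixels, provenance = list(
    colormap = cmap$name, inverted = cmap$inverted,
    vmin = range$vmin, vmax = range$vmax, units = range$units,
    scale = range$scale, log_floor = range$log_floor, kind = qmap$kind))
}

#' Default color-bar tick values
#'
#' Round numbers of the form `{1, 2, 5} x 10^k` inside the window, with
#' both endpoints always included.
#'
#' @param range a [value_range()].
#' @return sorted numeric tick values within `[vmin, vmax]`.
#' @export
default_ticks <- function(range) {
  stopifnot(inherits(range, "value_range"))
  ks <- seq(floor(log10(range$vmin)) - 1, ceiling(log10(range$vmax)) + 1)
  cand <- as.vector(outer(c(1, 2, 5), 10^ks))
  cand <- cand[cand >= range$vmin & cand <= range$vmax]
  sort(unique(c(range$vmin, cand, range$vmax)))
}

.fmt_value <- function(v) {
  formatC(v, format = "fg", digits = 7, big.mark = "")
}

#' Render a color bar
#'
#' A vertical or horizontal strip sweeping all colormap entries, with tick
#' marks, numeric labels and the units string. Every quantitative map must
#' be displayed alongside such a bar. In the recommended style each tick is
#' drawn at the bar position `value_to_position(tick)`, so on a
#' logarithmic display round-number labels sit at their true perceptual
#' positions; the `"legacy-linear-labels"` style places the same values at
#' their linear positions instead (for comparison figures only).
#'
#' @param cmap a `relax_cmap`.
#' @param range a [value_range()]; its `units` string is rendered next to
#'   the bar and must be non-empty.
#' @param ticks numeric tick values in `[vmin, vmax]` (at least the two
#'   endpoints); default [default_ticks()].
#' @param orientation `"vertical"` (vmax at top) or `"horizontal"` (vmax at
#'   right).
#' @param length_px,thickness_px bar geometry in pixels.
#' @param style tick-placement style, see above.
#' @param text_scale integer font magnification.
#' @return a `rendered_image`; tick values and positions are recorded in
#'   its provenance.
#' @export
render_colorbar <- function(cmap, range, ticks = NULL,
                            orientation = c("vertical", "horizontal"),
                            length_px = 256, thickness_px = 24,
                            style = c("recommended", "legacy-linear-labels"),
                            text_scale = 1L) {
  stopifnot(inherits(cmap, "relax_cmap"), inherits(range, "value_range"))
  orientation <- match.arg(orientation)
  style <- match.arg(style)
  if (!nzchar(range$units)) {
    stop("a color bar requires a non-empty units label", call. = FALSE)
  }
  if (is.null(ticks)) ticks <- default_ticks(range)
  ticks <- sort(unique(as.numeric(ticks)))
  if (any(ticks < range$vmin | ticks > range$vmax)) {
    stop("tick values must lie within [vmin, vmax]", call. = FALSE)
  }
  if (length(ticks) < 2L || ticks[1L] > range$vmin || ticks[length(ticks)] < range$vmax) {
    ticks <- sort(unique(c(range$vmin, ticks, range$vmax)))
  }
  pos <- if (style == "recommended") {
    value_to_position(ticks, range)
  } else {
    (ticks - range$vmin) / (range$vmax - range$vmin)
  }

  n <- nrow(cmap$entries)
  strip_idx <- position_to_entry(seq(0, 1, length.out = length_px), n) + 1L
  glyph_h <- 7L * text_scale
  tick_len <- 4L
  labels <- .fmt_value(ticks)
  label_rasters <- lapply(labels, .rasterize_text, scale = text_scale)
  units_raster <- .rasterize_text(range$units, scale = text_scale)
  text_w <- max(vapply(c(label_rasters, list(units_raster)), ncol, 1L)) + 4L
  margin <- glyph_h # room for labels at the bar ends

  if (orientation == "vertical") {
    H <- length_px + 2L * margin + glyph_h + 4L
    W <- thickness_px + tick_len + text_w
    canvas <- array(0, dim = c(H, W, 3L))
    bar_top <- margin + glyph_h + 4L
    rows <- bar_top + (length_px - 1L) - (seq_len(length_px) - 1L) # p=0 at bottom
    for (ch in 1:3) {
      canvas[rows, seq_len(thickness_px), ch] <-
        matrix(cmap$entries[strip_idx, ch], length_px, thickness_px)
    }
    for (i in seq_along(ticks)) {
      r <- bar_top + round((1 - pos[i]) * (length_px - 1L))
      canvas[r, thickness_px + seq_len(tick_len), ] <- 1
      canvas <- .blit(canvas, label_rasters[[i]],
                      row = r - floor(glyph_h / 2L),
                      col = thickness_px + tick_len + 3L)
    }
    canvas <- .blit(canvas, units_raster, row = 2L, col = 2L)
  } else {
    H <- thickness_px + tick_len + glyph_h + 4L
    W <- length_px + 2L * margin
    canvas <- array(0, dim = c(H, W, 3L))
    bar_left <- margin
    cols <- bar_left + seq_len(length_px) - 1L # p=0 at left
    for (ch in 1:3) {
      canvas[seq_len(thickness_px), cols, ch] <-
        matrix(cmap$entries[strip_idx, ch], thickness_px, length_px,
               byrow = TRUE)
    }
    for (i in seq_along(ticks)) {
      cpx <- bar_left + round(pos[i] * (length_px - 1L))
      canvas[thickness_px + seq_len(tick_len), cpx, ] <- 1
      lw <- ncol(label_rasters[[i]])
      canvas <- .blit(canvas, label_rasters[[i]],
                      row = thickness_px + tick_len + 2L,
                      col = cpx - floor(lw / 2L))
    }
    canvas <- .blit(canvas, units_raster,
                    row = thickness_px + tick_len + 2L,
                    col = W - ncol(units_raster) - 2L)
  }
  .new_image(canvas, provenance = list(
    colormap = cmap$name, vmin = range$vmin, vmax = range$vmax,
    units = range$units, scale = range$scale, style = style,
    orientation = orientation,
    tick_values = ticks, tick_positions = pos))
}

#' Compose a map image and its color bar into one panel
#'
#' Side-by-side (or stacked) composition on a black background. The map
#' pixels are preserved bit-exactly. Composition with the bar is the
#' default export path; bar-less export requires an explicit opt-out at
#' the CLI level, keeping "always display with a color bar" the path of
#' least resistance.
#'
#' @param image the rendered map.
#' @param bar the rendered color bar.
#' @param side where the bar goes: `"right"` or `"bottom"`.
#' @param gutter_px black gap between map and bar.
#' @return a `rendered_image`.
#' @export
compose_panel <- function(image, bar, side = c("right", "bottom"),
                          gutter_px = 8) {
  stopifnot(inherits(image, "rendered_image"), inherits(bar, "rendered_image"))
  side <- match.arg(side)
  a <- image$pixels; b <- bar$pixels
  if (side == "right") {
    H <- max(dim(a)[1L], dim(b)[1L])
    W <- dim(a)[2L] + gutter_px + dim(b)[2L]
    canvas <- array(0, dim = c(H, W, 3L))
    canvas[seq_len(dim(a)[1L]), seq_len(dim(a)[2L]), ] <- a
    canvas[seq_len(dim(b)[1L]), dim(a)[2L] + gutter_px + seq_len(dim(b)[2L]), ] <- b
  } else {
    W <- max(dim(a)[2L], dim(b)[2L])
    H <- dim(a)[1L] + gutter_px + dim(b)[1L]
    canvas <- array(0, dim = c(H, W, 3L))
    canvas[seq_len(dim(a)[1L]), seq_len(dim(a)[2L]), ] <- a
    canvas[dim(a)[1L] + gutter_px + seq_len(dim(b)[1L]), seq_len(dim(b)[2L]), ] <- b
  }
  prov <- image$provenance
  prov$colorbar <- TRUE
  prov$tick_values <- bar$provenance$tick_values
  .new_image(canvas, provenance = prov)
}

#' Render a complete display panel
#'
#' One-call pipeline: [render_map()] plus, by default, [render_colorbar()]
#' and [compose_panel()].
#'
#' @inheritParams render_map
#' @param colorbar include the color bar (default and recommended).
#' @param ticks optional tick values for the bar.
#' @param side bar placement.
#' @return a `rendered_image`.
#' @export
render_panel <- function(qmap, cmap, range, colorbar = TRUE, ticks = NULL,
                         side = "right") {
  img <- render_map(qmap, cmap, range)
  if (!colorbar) return(img)
  bar <- render_colorbar(cmap, range, ticks = ticks,
                         length_px = max(128L, nrow(qmap$values)))
  compose_panel(img, bar, side = side)
}

#' Write a rendered image as PNG (with provenance sidecar)
#'
#' @param img a `rendered_image`.
#' @param path output PNG path.
#' @param sidecar write `<path>.txt` with key:value provenance lines.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path, sidecar = TRUE) {
  stopifnot(inherits(img, "rendered_image"))
  png::writePNG(img$pixels, path)
  if (sidecar) {
    p <- img$provenance
    lines <- vapply(names(p), function(k) {
      paste0(k, ": ", paste(format(p[[k]]), collapse = " "))
    }, character(1))
    writeLines(lines, paste0(path, ".txt"))
  }
  invisible(path)
}
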