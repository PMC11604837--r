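# Colormap construction: a smooth CIELAB path through anchor colors,
# iteratively reparameterized until successive CIEDE2000 steps are uniform.
#
# The procedure: sample the anchor path densely, compute successive
# perceptual differences between the output colors, form their cumulative
# sum, divide it into equally spaced levels, and map those levels back onto
# the path by linear interpolation of the cumulative contrast curve;
# repeat until the coefficient of variation of the local contrast drops
# below a threshold.

#' Define an anchor set for colormap construction
#'
#' An ordered list of characteristic colors (default designs use five,
#' evenly spread in lightness) through which the colormap's CIELAB path
#' must pass. The builder requires strictly monotone lightness across the
#' anchors — the property that keeps the final map luminance-monotone and
#' hence readable under any color-vision deficiency. Non-monotone sets
#' (jet-style) are rejected here but remain auditable via
#' [uniformity_report()].
#'
#' @param colors an n x 3 matrix: sRGB channels in `[0, 1]`
#'   (`space = "srgb"`) or CIELAB rows (`space = "lab"`).
#' @param name label for the resulting colormap.
#' @param space color space of `colors`.
#' @return an object of class `anchor_set` holding the CIELAB anchors.
#' @export
anchor_set <- function(colors, name = "custom", space = c("srgb", "lab")) {
  space <- match.arg(space)
  colors <- .as_color_matrix(colors, "anchor colors")
  if (nrow(colors) < 2L) stop("need at least 2 anchors", call. = FALSE)
  lab <- if (space == "srgb") srgb_to_lab(colors) else colors
  if (space == "lab") {
    srgb <- lab_to_srgb(lab)
    if (any(attr(srgb, "out_of_gamut"))) {
      stop("anchor(s) ", paste(which(attr(srgb, "out_of_gamut")), collapse = ", "),
           " lie outside the sRGB gamut", call. = FALSE)
    }
  }
  dL <- diff(lab[, 1L])
  if (!(all(dL > 0) || all(dL < 0))) {
    stop("anchor lightness must be strictly monotone ",
         "(jet-style anchor sets are not buildable)", call. = FALSE)
  }
  structure(list(lab = lab, name = name), class = "anchor_set")
}

#' Built-in anchor presets
#'
#' Five-anchor sets with evenly spread lightness (L* 12 to 96) whose hue
#' trajectories approximate the overall look of the two recommended
#' relaxometry colormaps: `"lipari-like"` runs dark blue - violet - mauve -
#' salmon - pale yellow (for T1/R1 display), `"navia-like"` runs dark blue -
#' blue - teal - green - pale yellow-green (for T2/T2*/R2/R2* display).
#' They are approximations of the published designs, not reproductions; use
#' [read_colormap()] to audit the published tables themselves. The dark end
#' starts at L* = 12 with blue chroma, which keeps the first valid color at
#' a CIEDE2000 distance well above 10 from the black invalidity color.
#'
#' @param name `"lipari-like"` or `"navia-like"`.
#' @return an `anchor_set`.
#' @export
preset_anchors <- function(name = c("lipari-like", "navia-like")) {
  name <- match.arg(name)
  lab <- switch(name,
    "lipari-like" = rbind(
      c(12, 14, -26),
      c(33, 28, -38),
      c(54, 42, 5),
      c(75, 24, 32),
      c(96, 0, 14)),
    "navia-like" = rbind(
      c(12, 8, -28),
      c(33, -2, -32),
      c(54, -28, 2),
      c(75, -30, 38),
      c(96, -8, 20)))
  anchor_set(lab, name = name, space = "lab")
}

# Linear interpolation of a dense Lab polyline at parameter values u in [0,1].
.path_at <- function(path, u) {
  t <- attr(path, "param")
  cbind(L = stats::approx(t, path[, 1L], u, rule = 2)$y,
        a = stats::approx(t, path[, 2L], u, rule = 2)$y,
        b = stats::approx(t, path[, 3L], u, rule = 2)$y)
}

#' Fit a smooth CIELAB path through anchor colors
#'
#' Monotone piecewise-cubic (Fritsch-Carlson) interpolation per CIELAB
#' coordinate against the chord-length parameter, sampled at `n_dense`
#' points. The monotone form avoids the overshoot that ordinary cubic
#' splines produce between saturated anchors, which is what would push the
#' path outside the sRGB gamut. Endpoints coincide exactly with the first
#' and last anchors; with two anchors the path is a straight CIELAB
#' segment.
#'
#' @param anchors an [anchor_set()].
#' @param n_dense number of samples; must be well above the final colormap
#'   resolution for stable arc-length inversion (default 4096).
#' @param gamut_tol maximum tolerated linear-RGB excursion outside `[0, 1]`
#'   before the path is rejected.
#' @return an `n_dense` x 3 Lab matrix with attribute `param` (the
#'   normalized arc parameter of each sample).
#' @export
fit_anchor_path <- function(anchors, n_dense = 4096, gamut_tol = 0.005) {
  stopifnot(inherits(anchors, "anchor_set"))
  lab <- anchors$lab
  n <- nrow(lab)
  chord <- sqrt(rowSums(diff(lab)^2))
  if (any(chord == 0)) stop("duplicate consecutive anchors", call. = FALSE)
  t <- c(0, cumsum(chord)) / sum(chord)
  u <- seq(0, 1, length.out = n_dense)
  if (n == 2L) {
    path <- cbind(stats::approx(t, lab[, 1L], u)$y,
                  stats::approx(t, lab[, 2L], u)$y,
                  stats::approx(t, lab[, 3L], u)$y)
  } else {
    path <- sapply(1:3, function(j) {
      stats::splinefun(t, lab[, j], method = "monoH.FC")(u)
    })
  }
  dimnames(path) <- list(NULL, c("L", "a", "b"))
  # reject paths that stray out of gamut beyond tolerance
  fy <- (path[, 1L] + 16) / 116
  f <- cbind(fy + path[, 2L] / 500, fy, fy - path[, 3L] / 200)
  lin <- sweep(.lab_finv(f), 2L, .WHITE, "*") %*% t(.XYZ2RGB)
  exc <- pmax(apply(-lin, 1L, max), apply(lin - 1, 1L, max), 0)
  if (max(exc) > gamut_tol) {
    bad <- which.max(exc)
    stop(sprintf(paste0("anchor path leaves the sRGB gamut at parameter ",
                        "u = %.4f (excursion %.4f in linear RGB)"),
                 u[bad], exc[bad]), call. = FALSE)
  }
  attr(path, "param") <- u
  path
}

#' Equalize perceptual contrast along a colormap path
#'
#' Selects `n_out` colors on a dense CIELAB path and iteratively respaces
#' them so the successive CIEDE2000 differences become uniform: at each
#' iteration the cumulative sum of successive differences is divided into
#' `n_out` equally spaced levels, which are mapped back onto the path by
#' linear interpolation of the cumulative contrast curve. Iteration stops
#' when the coefficient of variation (sd/mean) of the successive
#' differences drops below `tol`.
#'
#' @param path dense Lab polyline from [fit_anchor_path()].
#' @param n_out number of output colors (256 for the recommended maps).
#' @param tol target coefficient of variation of successive CIEDE2000 steps.
#' @param max_iter iteration cap; on non-convergence the map is returned
#'   with a warning and the achieved CV recorded in `$build`.
#' @param name passed to [colormap()].
#' @return a `relax_cmap` with build diagnostics in `$build`.
#' @export
equalize_contrast <- function(path, n_out = 256, tol = 0.01, max_iter = 50,
                              name = "built") {
  stopifnot(is.matrix(path), ncol(path) == 3L, !is.null(attr(path, "param")))
  if (n_out < 2L) stop("n_out must be at least 2", call. = FALSE)
  u <- seq(0, 1, length.out = n_out)
  cv <- Inf
  iter <- 0L
  lab <- .path_at(path, u)
  repeat {
    d <- .successive_delta_e(lab)
    m <- mean(d)
    if (m == 0) stop("degenerate path: zero total contrast", call. = FALSE)
    cv <- stats::sd(d) / m
    if (cv <= tol || iter >= max_iter) break
    iter <- iter + 1L
    cum <- c(0, cumsum(d))
    target <- seq(0, cum[n_out], length.out = n_out)
    u <- stats::approx(cum, u, target, ties = "ordered")$y
    lab <- .path_at(path, u)
  }
  converged <- cv <= tol
  if (!converged) {
    warning(sprintf("equalization did not reach CV <= %g in %d iterations (achieved %.4g)",
                    tol, max_iter, cv))
  }
  srgb <- lab_to_srgb(lab)
  attr(srgb, "out_of_gamut") <- NULL
  colormap(srgb, name = name, source = "built",
           build = list(cv = cv, iterations = iter, converged = converged,
                        tol = tol))
}

#' Build a perceptually linearized colormap from anchors
#'
#' Convenience pipeline: [fit_anchor_path()] then [equalize_contrast()].
#'
#' @inheritParams fit_anchor_path
#' @inheritParams equalize_contrast
#' @return a `relax_cmap` of `n_out` entries.
#' @export
#' @examples
#' cm <- build_colormap(preset_anchors("navia-like"))
#' uniformity_report(cm)
build_colormap <- function(anchors, n_out = 256, tol = 0.01, max_iter = 50,
                           n_dense = 4096, gamut_tol = 0.005) {
  path <- fit_anchor_path(anchors, n_dense = n_dense, gamut_tol = gamut_tol)
  equalize_contrast(path, n_out = n_out, tol = tol, max_iter = max_iter,
                    name = anchors$name)
}
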