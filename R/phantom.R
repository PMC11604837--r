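# Synthetic relaxometry phantoms: 2D maps with known geometry and values so
# the display pipeline is testable without clinical data. Background pixels
# carry the invalidity sentinel 0; region values are strictly positive.

.TIME_KINDS <- c("T1", "T2", "T2*")
.RATE_KINDS <- c("R1", "R2", "R2*")

#' Create a quantitative map object
#'
#' @param values numeric matrix in map units; 0 (or NaN) marks pixels where
#'   no relaxation value is known (the invalidity sentinel, always rendered
#'   black).
#' @param kind one of T1, T2, T2*, R1, R2, R2*.
#' @param units `"ms"` for time kinds, `"1/s"` for rate kinds.
#' @return an object of class `quant_map`.
#' @export
quant_map <- function(values, kind = "T1", units = NULL) {
  kind <- match.arg(kind, c(.TIME_KINDS, .RATE_KINDS))
  if (is.null(units)) units <- if (kind %in% .TIME_KINDS) "ms" else "1/s"
  expected <- if (kind %in% .TIME_KINDS) "ms" else "1/s"
  if (units != expected) {
    stop(sprintf("kind %s requires units '%s', got '%s'", kind, expected, units),
         call. = FALSE)
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  fin <- values[is.finite(values)]
  if (any(fin < 0)) stop("relaxation values must be >= 0", call. = FALSE)
  structure(list(values = values, kind = kind, units = units),
            class = "quant_map")
}

#' @export
print.quant_map <- function(x, ...) {
  nval <- sum(is.finite(x$values) & x$values > 0)
  cat(sprintf("<quant_map> %s [%s], %d x %d, %d valid / %d invalid pixels\n",
              x$kind, x$units, nrow(x$values), ncol(x$values),
              nval, length(x$values) - nval))
  invisible(x)
}

#' @rdname phantom_spec
#' @export
disk_region <- function(center, radius, value, noise_sd = 0) {
  list(shape = "disk", center = center, radius = radius,
       value = value, noise_sd = noise_sd)
}

#' @rdname phantom_spec
#' @export
annulus_region <- function(center, r_inner, r_outer, value, noise_sd = 0) {
  stopifnot(r_inner < r_outer)
  list(shape = "annulus", center = center, r_inner = r_inner,
       r_outer = r_outer, value = value, noise_sd = noise_sd)
}

#' @rdname phantom_spec
#' @export
rect_region <- function(rows, cols, value, noise_sd = 0) {
  list(shape = "rect", rows = rows, cols = cols,
       value = value, noise_sd = noise_sd)
}

#' Specify a synthetic relaxometry phantom
#'
#' A phantom is a grid of sentinel (0) background with geometric regions of
#' known relaxation value plus optional truncated-Gaussian noise (truncation
#' at 0 keeps values physical). Overlapping regions resolve last-wins.
#' Identical spec + seed always produces a bit-identical map.
#'
#' @param dim grid size `c(rows, cols)`.
#' @param regions list of regions from [disk_region()], [annulus_region()],
#'   [rect_region()]; centers/radii in pixel units (pixel centers at
#'   integers).
#' @param kind,units as in [quant_map()].
#' @param seed integer seed making generation deterministic.
#' @param center,radius disk/annulus center `c(row, col)` and radii, pixels.
#' @param r_inner,r_outer annulus radii.
#' @param rows,cols rectangle extents `c(first, last)`, inclusive.
#' @param value region relaxation value (map units, > 0).
#' @param noise_sd Gaussian noise SD (map units).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(128, 128), regions = list(), kind = "T1",
                         units = NULL, seed = 1L) {
  stopifnot(length(dim) == 2L, all(dim >= 1))
  for (r in regions) {
    if (!is.numeric(r$value) || r$value <= 0) {
      stop("region values must be > 0", call. = FALSE)
    }
    if (r$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  }
  structure(list(dim = as.integer(dim), regions = regions, kind = kind,
                 units = units, seed = as.integer(seed)),
            class = "phantom_spec")
}

.region_mask <- function(shape, dim) {
  rows <- matrix(seq_len(dim[1L]), dim[1L], dim[2L])
  cols <- matrix(seq_len(dim[2L]), dim[1L], dim[2L], byrow = TRUE)
  switch(shape$shape,
    disk = (rows - shape$center[1L])^2 + (cols - shape$center[2L])^2 <=
      shape$radius^2,
    annulus = {
      d2 <- (rows - shape$center[1L])^2 + (cols - shape$center[2L])^2
      d2 <= shape$r_outer^2 & d2 >= shape$r_inner^2
    },
    rect = rows >= shape$rows[1L] & rows <= shape$rows[2L] &
      cols >= shape$cols[1L] & cols <= shape$cols[2L],
    stop("unknown region shape '", shape$shape, "'", call. = FALSE))
}

#' Generate a phantom map
#'
#' @param spec a [phantom_spec()].
#' @return a [quant_map()]; background pixels are exactly 0.
#' @export
#' @examples
#' spec <- phantom_spec(c(64, 64),
#'   list(disk_region(c(32, 32), 20, value = 1000, noise_sd = 50)),
#'   kind = "T1", seed = 7)
#' generate_phantom(spec)
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  values <- matrix(0, spec$dim[1L], spec$dim[2L])
  for (r in spec$regions) {
    mask <- .region_mask(r, spec$dim)
    k <- sum(mask)
    if (k == 0L) next
    if (r$noise_sd == 0) {
      values[mask] <- r$value
    } else {
      v <- stats::rnorm(k, r$value, r$noise_sd)
      # truncate at > 0 by resampling (relaxation values are physical)
      while (any(bad <- v <= 0)) {
        v[bad] <- stats::rnorm(sum(bad), r$value, r$noise_sd)
      }
      values[mask] <- v
    }
  }
  quant_map(values, kind = spec$kind, units = spec$units)
}

#' Built-in phantom presets
#'
#' Illustrative relaxometry scenes (typical 3T magnitudes; inputs, never
#' asserted ground truth): `"brain-t1-like"` — white-matter, gray-matter
#' and CSF-like disks (approx. 850, 1400, 4000 ms); `"cartilage-t2-like"` —
#' cartilage-like annulus and fluid disk (approx. 35, 60 ms).
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param dim grid size.
#' @return a [phantom_spec()].
#' @export
phantom_preset <- function(name = c("brain-t1-like", "cartilage-t2-like"),
                           seed = 1L, dim = c(128, 128)) {
  name <- match.arg(name)
  c0 <- dim / 2
  r <- min(dim) / 2
  switch(name,
    "brain-t1-like" = phantom_spec(dim, list(
      disk_region(c0, 0.78 * r, value = 850, noise_sd = 40),
      annulus_region(c0, 0.62 * r, 0.78 * r, value = 1400, noise_sd = 60),
      disk_region(c0 + c(0.3, 0) * r, 0.16 * r, value = 4000, noise_sd = 120),
      disk_region(c0 - c(0.3, 0.1) * r, 0.12 * r, value = 1400, noise_sd = 60)
    ), kind = "T1", seed = seed),
    "cartilage-t2-like" = phantom_spec(dim, list(
      annulus_region(c0, 0.55 * r, 0.75 * r, value = 35, noise_sd = 3),
      disk_region(c0, 0.4 * r, value = 60, noise_sd = 5)
    ), kind = "T2", seed = seed))
}

#' Reciprocal of a quantitative map (time <-> rate)
#'
#' Elementwise `1/v` on valid pixels with the ms <-> 1/s unit factor 1000
#' applied; sentinel pixels stay sentinel; kind flips T1 <-> R1 etc.
#' Applying twice restores the original values.
#'
#' @param qmap a [quant_map()].
#' @return a [quant_map()] of the reciprocal kind.
#' @export
reciprocal_phantom <- function(qmap) {
  stopifnot(inherits(qmap, "quant_map"))
  flip <- c(T1 = "R1", T2 = "R2", "T2*" = "R2*",
            R1 = "T1", R2 = "T2", "R2*" = "T2*")
  valid <- is.finite(qmap$values) & qmap$values > 0
  out <- qmap$values
  out[!valid] <- 0
  out[valid] <- 1000 / qmap$values[valid]
  quant_map(out, kind = unname(flip[qmap$kind]))
}
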