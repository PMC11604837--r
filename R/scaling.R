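# Value-to-color scaling. The logarithmic variant never transforms the
# stored relaxation values: it reparameterizes the colormap lookup so that
# equal *ratios* of the mapped value give equal perceived color steps
# (Weber-Fechner reading of relaxation contrast). To keep the mapping
# defined as v -> 0+ (and avoid log(0)), a small positive floor is added
# inside the logarithm, so it is not a pure logarithm.

#' Define a display window
#'
#' @param vmin,vmax positive window bounds in map units (ms for relaxation
#'   times, 1/s for rates); values outside clamp to the colormap ends.
#' @param units unit label, e.g. `"ms"` or `"1/s"`; rendered next to every
#'   color bar.
#' @param scale `"linear"` or `"log"` (logarithm-processed display).
#' @param log_floor small positive offset `f` used inside the logarithm;
#'   `0` gives the pure logarithm. Default `vmax / 1e4`: vanishingly small
#'   within typical windows, yet finite so the mapping extends to v -> 0+.
#' @return an object of class `value_range`.
#' @export
#' @examples
#' value_range(400, 2000, "ms", scale = "log")
value_range <- function(vmin, vmax, units = "", scale = c("linear", "log"),
                        log_floor = NULL) {
  scale <- match.arg(scale)
  if (!is.numeric(vmin) || !is.numeric(vmax) || length(vmin) != 1L ||
      length(vmax) != 1L || !is.finite(vmin) || !is.finite(vmax)) {
    stop("vmin and vmax must be finite scalars", call. = FALSE)
  }
  if (!(0 < vmin && vmin < vmax)) {
    stop("need 0 < vmin < vmax", call. = FALSE)
  }
  if (is.null(log_floor)) {
    log_floor <- if (scale == "log") vmax / 1e4 else 0
  }
  if (!is.numeric(log_floor) || length(log_floor) != 1L || log_floor < 0) {
    stop("log_floor must be a single number >= 0", call. = FALSE)
  }
  structure(list(vmin = vmin, vmax = vmax, units = units, scale = scale,
                 log_floor = log_floor), class = "value_range")
}

#' @export
print.value_range <- function(x, ...) {
  cat(sprintf("<value_range> %g..%g %s (%s%s)\n", x$vmin, x$vmax, x$units,
              x$scale,
              if (x$scale == "log") sprintf(", floor %g", x$log_floor) else ""))
  invisible(x)
}

#' Parse a range specification string
#'
#' Accepts the form `"vmin:vmax:unit[:log|linear]"` used by the command
#' line, e.g. `"400:2000:ms:log"`.
#'
#' @param spec character scalar.
#' @return a [value_range()].
#' @export
parse_range <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  if (length(parts) < 3L || length(parts) > 4L) {
    stop("range must be 'vmin:vmax:unit[:log|linear]'", call. = FALSE)
  }
  vmin <- suppressWarnings(as.numeric(parts[1L]))
  vmax <- suppressWarnings(as.numeric(parts[2L]))
  if (is.na(vmin) || is.na(vmax)) {
    stop("non-numeric bounds in range specification", call. = FALSE)
  }
  scale <- if (length(parts) == 4L) parts[4L] else "linear"
  value_range(vmin, vmax, units = parts[3L], scale = scale)
}

#' Map a value to a colormap position
#'
#' Linear scale: `(v - vmin) / (vmax - vmin)`, clamped to `[0, 1]`.
#' Logarithmic scale:
#' `(log(v + f) - log(vmin + f)) / (log(vmax + f) - log(vmin + f))`,
#' clamped, with `f` the range's `log_floor`. Monotone increasing in `v`
#' on both scales. Invalid (sentinel) values must never reach this
#' function; valid values below `vmin` clamp to position 0 (the first
#' valid color, never black).
#'
#' @param v positive values in map units (vectorized).
#' @param range a [value_range()].
#' @return positions in `[0, 1]`.
#' @export
value_to_position <- function(v, range) {
  stopifnot(inherits(range, "value_range"))
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("value_to_position requires finite values > 0 (the sentinel never reaches the scale)",
         call. = FALSE)
  }
  p <- if (range$scale == "linear") {
    (v - range$vmin) / (range$vmax - range$vmin)
  } else {
    f <- range$log_floor
    (log(v + f) - log(range$vmin + f)) / (log(range$vmax + f) - log(range$vmin + f))
  }
  pmin(pmax(p, 0), 1)
}

#' Map a position to a colormap entry id
#'
#' Deterministic half-open binning: `floor(p * n)`, with `p = 1` closing
#' into the top bin. Entry ids are 0-based (0..n-1), matching the row
#' labelling of 256-entry colormap tables; R-side indexing adds 1.
#'
#' @param p positions in `[0, 1]`.
#' @param n number of colormap entries.
#' @return integer entry ids in `0..n-1`.
#' @export
position_to_entry <- function(p, n = 256) {
  if (any(p < 0 | p > 1)) stop("positions must lie in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  idx <- as.integer(floor(p * n))
  idx[idx == n] <- n - 1L
  idx
}

#' Reciprocal display window for rate maps
#'
#' A time window in ms maps to the rate window `(1000/vmax, 1000/vmin)` in
#' 1/s (and back); windows in s use factor 1. Scale kind is preserved; the
#' log floor is re-derived from the new `vmax` unless given.
#'
#' @param range a [value_range()].
#' @param log_floor optional explicit floor for the reciprocal range.
#' @return a [value_range()] in the reciprocal units.
#' @export
reciprocal_range <- function(range, log_floor = NULL) {
  stopifnot(inherits(range, "value_range"))
  conv <- switch(range$units,
                 "ms" = list(k = 1000, units = "1/s"),
                 "1/s" = list(k = 1000, units = "ms"),
                 "s" = list(k = 1, units = "1/s"),
                 stop("no reciprocal unit defined for '", range$units, "'",
                      call. = FALSE))
  # a pure-log source range stays pure log; otherwise the floor is
  # re-derived from the reciprocal window's own vmax
  if (is.null(log_floor) && range$log_floor == 0) log_floor <- 0
  value_range(conv$k / range$vmax, conv$k / range$vmin, units = conv$units,
              scale = range$scale, log_floor = log_floor)
}

#' Check the time/rate display duality
#'
#' With a pure logarithmic scale, displaying a time map on a window
#' `(a, b)` is exactly equivalent to displaying its reciprocal rate map on
#' the reciprocal window with the *inverted* colormap:
#' `position(v; a, b) + position(1/v; 1/b, 1/a) = 1`. A finite log floor
#' breaks the identity slightly; this function reports the worst-case
#' position discrepancy over a geometric grid of sampled values, so the
#' practical impact of the floor can be quantified.
#'
#' @param range_t a log-scale time [value_range()].
#' @param samples number of sampled values across the window.
#' @return maximum absolute position discrepancy (0 when `log_floor = 0`).
#' @export
verify_reciprocal_duality <- function(range_t, samples = 512) {
  stopifnot(inherits(range_t, "value_range"))
  if (range_t$scale != "log") {
    warning("duality holds only for logarithmic scaling; linear scales show large discrepancies")
  }
  conv_k <- switch(range_t$units, "ms" = 1000, "1/s" = 1000, "s" = 1,
                   stop("no reciprocal unit defined for '", range_t$units, "'",
                        call. = FALSE))
  range_r <- reciprocal_range(range_t)
  v <- exp(seq(log(range_t$vmin), log(range_t$vmax), length.out = samples))
  p_t <- value_to_position(v, range_t)
  p_r <- value_to_position(conv_k / v, range_r)
  max(abs(p_t - (1 - p_r)))
}
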