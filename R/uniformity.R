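# The auditor: perceptual-uniformity statistics, luminance monotonicity,
# black-margin and color-vision-deficiency checks for any colormap (built
# or loaded, including deliberately bad ones like jet).

.monotone <- function(v) {
  d <- diff(v)
  all(d > 0) || all(d < 0)
}

.delta_stats <- function(entries) {
  lab <- srgb_to_lab(entries)
  d <- .successive_delta_e(lab)
  list(deltas = d, mean = mean(d), cv = stats::sd(d) / mean(d),
       lum_monotone = .monotone(relative_luminance(entries)))
}

#' Audit a colormap for perceptual uniformity and CVD safety
#'
#' Computes the successive CIEDE2000 profile of a colormap together with
#' the properties the consensus recommendations require of a relaxometry
#' display map:
#' \itemize{
#'   \item mean and coefficient of variation of the 255 successive
#'     CIEDE2000 steps (a 256-level grayscale ramp averages about 0.29;
#'     the recommended maps about 0.44 — more contrast per step, spent
#'     evenly);
#'   \item strict luminance monotonicity (jet-style rainbows fail: their
#'     brightest color sits mid-range);
#'   \item the same statistics after simulating each color-vision
#'     deficiency, since perceptual linearity must survive CVD viewing;
#'   \item the black margin: CIEDE2000 distance of the first entry from
#'     black, reported raw and as a percentage of the full cumulative path
#'     length, so that the "first valid color clearly distinct from the
#'     black invalidity color" rule can be checked under either reading.
#' }
#'
#' @param cmap a `relax_cmap` (any map is accepted; only the builder
#'   enforces monotone-lightness anchors).
#' @param cvd_severity severity used for the CVD simulations.
#' @return an object of class `uniformity_report`.
#' @export
uniformity_report <- function(cmap, cvd_severity = 1) {
  stopifnot(inherits(cmap, "relax_cmap"))
  entries <- cmap$entries
  base <- .delta_stats(entries)
  cvd <- lapply(.CVD_KINDS, function(kind) {
    s <- .delta_stats(simulate_cvd(entries, kind, cvd_severity))
    list(mean_delta = s$mean, cv_delta = s$cv,
         luminance_monotone = s$lum_monotone)
  })
  names(cvd) <- .CVD_KINDS
  margin <- delta_e_ciede2000(srgb_to_lab(entries[1L, ]),
                              c(0, 0, 0))
  structure(list(
    name = cmap$name,
    n_entries = nrow(entries),
    successive_deltas = base$deltas,
    mean_delta = base$mean,
    cv_delta = base$cv,
    luminance_monotone = base$lum_monotone,
    cvd_results = cvd,
    black_margin_raw = as.numeric(margin),
    black_margin_pct = 100 * as.numeric(margin) / sum(base$deltas)
  ), class = "uniformity_report")
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(sprintf("<uniformity_report> %s (%d entries)\n", x$name, x$n_entries))
  cat(sprintf("  successive dE2000: mean %.4f, CV %.4f\n",
              x$mean_delta, x$cv_delta))
  cat(sprintf("  luminance monotone: %s\n",
              if (x$luminance_monotone) "yes" else "NO"))
  cat(sprintf("  black margin: dE2000 %.2f (%.1f%% of path length)\n",
              x$black_margin_raw, x$black_margin_pct))
  for (k in names(x$cvd_results)) {
    r <- x$cvd_results[[k]]
    cat(sprintf("  %-14s mean %.4f, CV %.4f, luminance monotone: %s\n",
                paste0(k, ":"), r$mean_delta, r$cv_delta,
                if (r$luminance_monotone) "yes" else "NO"))
  }
  invisible(x)
}

# Flat named list view used for machine-readable (JSON) audit output.
.report_as_list <- function(x) {
  list(
    name = x$name,
    n_entries = x$n_entries,
    mean_delta = x$mean_delta,
    cv_delta = x$cv_delta,
    luminance_monotone = x$luminance_monotone,
    black_margin_raw = x$black_margin_raw,
    black_margin_pct = x$black_margin_pct,
    cvd = x$cvd_results
  )
}
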