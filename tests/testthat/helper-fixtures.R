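# Shared fixtures. Building a 256-entry map costs ~1 s, so the preset maps
# are built once per test run and reused.

built_map <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) {
      cache[[name]] <<- build_colormap(preset_anchors(name))
    }
    cache[[name]]
  }
})

# Random in-gamut sRGB colors as an n x 3 matrix.
random_srgb <- function(n) matrix(stats::runif(3 * n), ncol = 3L)

# A small T1 phantom with all four value classes the renderer must handle:
# sentinel, below-window, in-window, at-window-top.
four_value_phantom <- function(vmin, vmax) {
  vals <- matrix(c(0, vmin, sqrt(vmin * vmax), vmax), nrow = 2)
  quant_map(vals, kind = "T1")
}
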