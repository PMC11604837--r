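# Rendering rules: the black sentinel, window clamping, deterministic
# rasters, the labelled color bar, panel composition, and the image-level
# time/rate duality.

test_that("all-sentinel maps render to pure black", {
  qmap <- quant_map(matrix(0, 8, 8), kind = "T1")
  img <- render_map(qmap, built_map("lipari-like"),
                    value_range(400, 2000, "ms", "log"))
  expect_identical(dim(img$pixels), c(8L, 8L, 3L))
  expect_true(all(img$pixels == 0))
})

test_that("NaN pixels are treated as the sentinel and render black", {
  vals <- matrix(c(NaN, 500, 1000, 0), 2)
  qmap <- quant_map(vals, kind = "T1")
  img <- render_map(qmap, built_map("lipari-like"),
                    value_range(400, 2000, "ms", "log"))
  expect_identical(img$pixels[1, 1, ], c(0, 0, 0))
  expect_identical(img$pixels[2, 2, ], c(0, 0, 0))
  expect_false(all(img$pixels[1, 2, ] == 0))
})

test_that("window endpoints and the geometric midpoint hit entries 0, 128, 255", {
  vmin <- 400; vmax <- 2000
  qmap <- four_value_phantom(vmin, vmax)
  cmap <- built_map("lipari-like")
  rng <- value_range(vmin, vmax, "ms", "log", log_floor = 0)
  img <- render_map(qmap, cmap, rng)
  # layout of four_value_phantom: [1,1]=0, [2,1]=vmin, [1,2]=geomean, [2,2]=vmax
  expect_identical(img$pixels[1, 1, ], c(0, 0, 0))
  expect_equal(img$pixels[2, 1, ], unname(cmap$entries[1, ]))
  expect_equal(img$pixels[1, 2, ], unname(cmap$entries[129, ]))
  expect_equal(img$pixels[2, 2, ], unname(cmap$entries[256, ]))
  # a constant map at vmax is wall-to-wall top entry
  flat <- quant_map(matrix(vmax, 4, 4), kind = "T1")
  imgf <- render_map(flat, cmap, rng)
  expect_true(all(apply(imgf$pixels, c(1, 2), function(px) {
    isTRUE(all.equal(px, unname(cmap$entries[256, ])))
  })))
})

test_that("valid values below the window clamp to entry 0, never to black", {
  qmap <- quant_map(matrix(c(0, 100), 1), kind = "T1") # 100 ms < vmin
  cmap <- built_map("lipari-like")
  img <- render_map(qmap, cmap, value_range(400, 2000, "ms", "log"))
  expect_identical(img$pixels[1, 1, ], c(0, 0, 0))
  expect_equal(img$pixels[1, 2, ], unname(cmap$entries[1, ]))
  expect_gt(sum(img$pixels[1, 2, ]), 0)
})

test_that("unit mismatch between map and window is rejected", {
  qmap <- quant_map(matrix(1000, 2, 2), kind = "T1")
  expect_error(render_map(qmap, built_map("lipari-like"),
                          value_range(0.5, 2.5, "1/s", "log")),
               "unit mismatch")
})

test_that("rendering is deterministic", {
  qmap <- generate_phantom(phantom_preset("brain-t1-like", seed = 8,
                                          dim = c(32, 32)))
  cmap <- built_map("lipari-like")
  rng <- value_range(400, 2000, "ms", "log")
  expect_identical(render_map(qmap, cmap, rng)$pixels,
                   render_map(qmap, cmap, rng)$pixels)
})

test_that("linear color-bar ticks sit at their linear offsets", {
  bar <- render_colorbar(grayscale_colormap(), value_range(0.5, 2.5, "1/s"),
                         ticks = c(0.5, 1.5, 2.5))
  expect_equal(bar$provenance$tick_positions, c(0, 0.5, 1))
  expect_identical(bar$provenance$units, "1/s")
})

test_that("log color-bar places 1200 ms at log(3)/log(5) of the bar", {
  rng <- value_range(400, 2000, "ms", "log", log_floor = 0)
  bar <- render_colorbar(built_map("lipari-like"), rng,
                         ticks = c(400, 1200, 2000))
  expect_equal(bar$provenance$tick_positions[2], log(3) / log(5),
               tolerance = 1e-12)
  # legacy style places the same value linearly instead
  leg <- render_colorbar(built_map("lipari-like"), rng,
                         ticks = c(400, 1200, 2000),
                         style = "legacy-linear-labels")
  expect_equal(leg$provenance$tick_positions[2], 0.5)
})

test_that("color bars carry readable numbers and a units label", {
  rng <- value_range(400, 2000, "ms", "log")
  bar <- render_colorbar(built_map("navia-like"), rng)
  # default round-number ticks include the forced endpoints
  expect_true(all(c(400, 2000) %in% bar$provenance$tick_values))
  expect_true(all(c(500, 1000) %in% bar$provenance$tick_values))
  # tick marks and glyph pixels are drawn in pure white outside the strip
  strip_w <- 24 # default thickness_px
  text_zone <- bar$pixels[, (strip_w + 1):dim(bar$pixels)[2], ]
  expect_gt(sum(text_zone == 1), 50)
  # an empty units label violates the display rules
  expect_error(render_colorbar(built_map("navia-like"),
                               value_range(1, 2, "", "linear")),
               "units")
  expect_error(render_colorbar(built_map("navia-like"), rng, ticks = c(100, 2000)),
               "within")
})

test_that("panel composition preserves map pixels and adds the bar by default", {
  qmap <- generate_phantom(phantom_preset("brain-t1-like", seed = 8,
                                          dim = c(48, 48)))
  cmap <- built_map("lipari-like")
  rng <- value_range(400, 2000, "ms", "log")
  img <- render_map(qmap, cmap, rng)
  bar <- render_colorbar(cmap, rng)
  panel <- compose_panel(img, bar, gutter_px = 8)
  expect_identical(dim(panel$pixels)[2],
                   dim(img$pixels)[2] + 8L + dim(bar$pixels)[2])
  expect_identical(panel$pixels[1:48, 1:48, ], img$pixels)
  expect_true(panel$provenance$colorbar)
  # the one-call wrapper includes the bar unless explicitly disabled
  p1 <- render_panel(qmap, cmap, rng)
  expect_gt(dim(p1$pixels)[2], dim(img$pixels)[2])
  p0 <- render_panel(qmap, cmap, rng, colorbar = FALSE)
  expect_identical(dim(p0$pixels), dim(img$pixels))
})

test_that("a log-displayed T1 map matches its inverted-map R1 rendering", {
  t1 <- generate_phantom(phantom_preset("brain-t1-like", seed = 13,
                                        dim = c(64, 64)))
  r1 <- reciprocal_phantom(t1)
  cmap <- built_map("lipari-like")
  rng_t <- value_range(400, 2000, "ms", "log")
  rng_r <- reciprocal_range(rng_t) # 0.5..2.5 1/s
  img_t <- render_map(t1, cmap, rng_t)
  img_r <- render_map(r1, invert_colormap(cmap), rng_r)
  px_t <- matrix(img_t$pixels, ncol = 3)
  px_r <- matrix(img_r$pixels, ncol = 3)
  de <- delta_e_ciede2000(srgb_to_lab(px_t), srgb_to_lab(px_r))
  expect_lte(max(de), 1)
})

test_that("PNG export round-trips the raster at 8-bit precision", {
  qmap <- four_value_phantom(400, 2000)
  panel <- render_panel(qmap, built_map("navia-like"),
                        value_range(400, 2000, "ms", "log"))
  path <- withr::local_tempfile(fileext = ".png")
  write_image_png(panel, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".txt")))
  back <- png::readPNG(path)
  expect_lt(max(abs(back - panel$pixels)), 1 / 255)
  sidecar <- readLines(paste0(path, ".txt"))
  expect_true(any(grepl("^colormap: navia-like", sidecar)))
  expect_true(any(grepl("^units: ms", sidecar)))
})
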