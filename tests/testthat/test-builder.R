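# Anchor-path fitting, contrast equalization (with an independent
# arc-length-inversion oracle), and the uniformity auditor.

test_that("two anchors give a straight CIELAB segment", {
  a <- anchor_set(rbind(c(20, 2, -5), c(85, 0, 10)), space = "lab")
  path <- fit_anchor_path(a, n_dense = 1001)
  mid <- path[501, ]
  expect_equal(as.numeric(mid), as.numeric((a$lab[1, ] + a$lab[2, ]) / 2),
               tolerance = 1e-9)
  expect_equal(as.numeric(path[1, ]), as.numeric(a$lab[1, ]))
  expect_equal(as.numeric(path[1001, ]), as.numeric(a$lab[2, ]))
})

test_that("collinear anchors are reproduced without spurious curvature", {
  # five anchors on one straight Lab line
  t <- c(0, 0.2, 0.45, 0.8, 1)
  p0 <- c(20, -5, -18); p1 <- c(90, 5, 25)
  lab <- t(sapply(t, function(u) p0 + u * (p1 - p0)))
  path <- fit_anchor_path(anchor_set(lab, space = "lab"), n_dense = 2048)
  # distance of every sample from the straight line, as dE00 to its projection
  d <- sweep(path, 2, p0)
  dir <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  proj <- sweep(outer(as.numeric(d %*% dir), dir), 2, p0, "+")
  dev <- delta_e_ciede2000(path, proj)
  expect_lt(max(dev), 0.5)
})

test_that("the dense path passes through all five anchors", {
  for (nm in c("lipari-like", "navia-like")) {
    anchors <- preset_anchors(nm)
    path <- fit_anchor_path(anchors)
    for (i in seq_len(nrow(anchors$lab))) {
      d <- delta_e_ciede2000(path, anchors$lab[i, ])
      expect_lt(min(d), 0.1)
    }
  }
})

test_that("builder rejects non-monotone lightness and out-of-gamut input", {
  # jet-style anchors: lightness rises to yellow mid-range then falls
  jet_anchors <- rbind(c(0, 0, 1), c(0, 1, 1), c(1, 1, 0), c(1, 0, 0))
  expect_error(anchor_set(jet_anchors, space = "srgb"), "monotone")
  expect_error(anchor_set(rbind(c(10, 0, 0), c(50, 150, -100), c(95, 0, 0)),
                          space = "lab"), "gamut")
  # individually in-gamut anchors whose spline segment exits the gamut near
  # the pale end must be rejected with the offending parameter location
  near_edge <- rbind(c(12, 14, -26), c(33, 28, -38), c(54, 42, 5),
                     c(75, 26, 34), c(96, 0, 14))
  expect_error(fit_anchor_path(anchor_set(near_edge, space = "lab")),
               "gamut at parameter")
})

test_that("equalization respaces a quadratic lightness ramp to match the arc-length oracle", {
  # path: neutral axis traversed quadratically in the parameter
  n_dense <- 4096
  u <- seq(0, 1, length.out = n_dense)
  path <- cbind(L = 100 * u^2, a = 0, b = 0)
  attr(path, "param") <- u
  n_out <- 64
  cm <- equalize_contrast(path, n_out = n_out, tol = 0.01, name = "quad")
  expect_s3_class(cm, "relax_cmap")
  d <- delta_e_ciede2000(srgb_to_lab(cm$entries[-n_out, ]),
                         srgb_to_lab(cm$entries[-1, ]))
  expect_lte(stats::sd(d) / mean(d), 0.01)

  # oracle: dense numeric inversion of the cumulative dE00 arc length along
  # the neutral axis, independent of the iterative remapping under test
  Lg <- seq(0, 100, length.out = 20001)
  dg <- delta_e_ciede2000(cbind(Lg[-length(Lg)], 0, 0), cbind(Lg[-1], 0, 0))
  cum <- c(0, cumsum(dg))
  L_oracle <- stats::approx(cum, Lg, seq(0, cum[length(cum)],
                                         length.out = n_out))$y
  L_got <- srgb_to_lab(cm$entries)[, "L"]
  expect_lt(max(abs(L_got - L_oracle)), 0.2)
})

test_that("an already-equalized path is a fixed point of the iteration", {
  # start from the oracle-equalized neutral ramp: CV is already ~0
  Lg <- seq(0, 100, length.out = 20001)
  dg <- delta_e_ciede2000(cbind(Lg[-length(Lg)], 0, 0), cbind(Lg[-1], 0, 0))
  cum <- c(0, cumsum(dg))
  L_eq <- stats::approx(cum, Lg, seq(0, cum[length(cum)], length.out = 2048))$y
  path <- cbind(L = L_eq, a = 0, b = 0)
  attr(path, "param") <- seq(0, 1, length.out = 2048)
  cm <- equalize_contrast(path, n_out = 64, tol = 0.01, name = "fixed")
  u64 <- seq(0, 1, length.out = 64)
  lab0 <- cbind(stats::approx(attr(path, "param"), path[, 1], u64)$y, 0, 0)
  moved <- delta_e_ciede2000(srgb_to_lab(cm$entries), lab0)
  d <- delta_e_ciede2000(srgb_to_lab(cm$entries[-64, ]),
                         srgb_to_lab(cm$entries[-1, ]))
  expect_lt(max(moved), 0.01 * mean(d))
})

test_that("built preset maps satisfy the construction contract", {
  for (nm in c("lipari-like", "navia-like")) {
    cm <- built_map(nm)
    expect_identical(nrow(cm$entries), 256L)
    expect_true(cm$build$converged)
    rep <- uniformity_report(cm)
    expect_lte(rep$cv_delta, 0.01)
    expect_true(rep$luminance_monotone)
    # black margin: first valid color clearly distinct from the invalidity
    # color, raw dE00 reading of the ">= 10% from black" rule
    expect_gte(rep$black_margin_raw, 10)
    expect_gt(rep$black_margin_pct, 10)
    # CVD safety: the luminance component stays monotone and local contrast
    # never collapses under full deuteranopia
    expect_true(rep$cvd_results$deuteranopia$luminance_monotone)
    sim <- simulate_cvd(cm$entries, "deuteranopia", 1)
    dsim <- delta_e_ciede2000(srgb_to_lab(sim[-256, ]), srgb_to_lab(sim[-1, ]))
    expect_gt(min(dsim), 0.1)
  }
})

test_that("equalization is idempotent on its own output", {
  for (nm in c("lipari-like", "navia-like")) {
    cm <- built_map(nm)
    path <- srgb_to_lab(cm$entries)
    attr(path, "param") <- seq(0, 1, length.out = 256)
    cm2 <- equalize_contrast(path, n_out = 256, tol = 0.01, name = "again")
    moved <- delta_e_ciede2000(srgb_to_lab(cm2$entries), srgb_to_lab(cm$entries))
    expect_lt(max(moved), 0.1)
  }
})

test_that("inversion is an involution that swaps ends and preserves the audit", {
  cm <- built_map("lipari-like")
  inv <- invert_colormap(cm)
  expect_true(inv$inverted)
  expect_identical(inv$entries[1, ], cm$entries[256, ])
  expect_identical(inv$entries[256, ], cm$entries[1, ])
  back <- invert_colormap(inv)
  expect_identical(back$entries, cm$entries)
  expect_identical(back$name, cm$name)
  expect_equal(uniformity_report(inv)$mean_delta,
               uniformity_report(cm)$mean_delta, tolerance = 1e-12)
})

test_that("the auditor accepts and flags maps the builder would reject", {
  rj <- uniformity_report(jet_colormap())
  expect_false(rj$luminance_monotone)
  rg <- uniformity_report(grayscale_colormap())
  expect_true(rg$luminance_monotone)
  expect_length(rg$successive_deltas, 255L)
  expect_gte(rg$cv_delta, 0)
  # grayscale steps are far from perceptually uniform
  expect_gt(rg$cv_delta, 0.1)
})
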