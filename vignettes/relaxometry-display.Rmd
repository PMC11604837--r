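---
title: "Methods: perceptually linearized display of relaxometry maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perceptually linearized display of relaxometry maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relcolor)
```

## The display model

A colormap is a function from a scalar display window onto a path through
a three-dimensional color space, discretized here to 256 entries. All
perceptual arithmetic in this package happens in CIELAB under D65 with
the 2° observer (the white point is not stated by the CIE Lab definition
itself; D65 is the one consistent with the sRGB standard the output is
encoded in), and all perceptual distances are CIEDE2000 with parametric
factors $k_L = k_C = k_H = 1$, the reference condition. One ΔE₀₀ unit is
roughly a just-noticeable difference. CIEDE2000 is symmetric and
non-negative but does not satisfy the triangle inequality, so it is used
strictly as a local difference measure, never as a metric.

### Building a map

1. **Anchors.** The designer supplies ≥2 anchor colors (the shipped
   presets use five) with strictly monotone lightness. Monotone lightness
   is what ultimately makes the map readable under color-vision
   deficiency: the luminance channel survives every dichromacy.
2. **Path.** A C¹ path through the anchors is fit by monotone
   piecewise-cubic (Fritsch–Carlson) interpolation of each CIELAB
   coordinate against the chord-length parameter, sampled at
   `n_dense = 4096` points. The monotone form was chosen over a natural
   cubic spline because ordinary splines overshoot between saturated
   anchors, and overshoot in Lab means leaving the sRGB gamut. The dense
   resolution must be well above the final 256 levels for the arc-length
   inversion below to be stable; 4096 (16×) makes the interpolation error
   negligible relative to one output step.
3. **Equalization.** 256 samples on the path are respaced iteratively:
   compute the 255 successive ΔE₀₀ steps, form their cumulative sum,
   divide it into 256 equally spaced levels, and map those levels back to
   path parameters by linear interpolation of the cumulative contrast
   curve. Iteration stops when the coefficient of variation (sd/mean) of
   the steps drops below `tol = 0.01` (the threshold is a package
   default; with a 4096-point path one iteration typically reaches CV
   below 10⁻³), or after `max_iter = 50` iterations, in which case the
   map is returned with a warning and the achieved CV recorded.
4. **Export.** Internal math is floating point throughout; conversion to
   encoded sRGB happens per entry, and 8-bit quantization (half-up,
   idempotent) only at file export.

### Gamut handling

`lab_to_srgb()` clips out-of-gamut colors channel-wise in linear RGB and
flags them. The builder uses the flag to *reject* paths that stray more
than `gamut_tol = 0.005` (linear-RGB units) outside the gamut, reporting
the offending path parameter, rather than silently bending the design.
Clipping was chosen over chroma-reduction gamut mapping because anchors
are chosen in-gamut and rejection makes excursions visible to the
designer instead of papering over them.

### Auditing

`uniformity_report()` accepts any colormap — built, loaded from a table,
or deliberately bad (a jet-style rainbow, an equal-step grayscale ramp).
It reports:

* the successive ΔE₀₀ profile, its mean (contrast per step) and CV
  (evenness of contrast);
* strict luminance monotonicity of `relative_luminance()` (the Y row of
  the sRGB→XYZ matrix), in either direction since both orientations of a
  map are legitimate;
* the **black margin**: ΔE₀₀ between entry 1 and black, reported both
  raw and as a percentage of the cumulative path length. The design rule
  "the first valid color must be clearly distinct from the black
  invalidity color, at least 10 % distant" is ambiguous about its scale,
  so both readings are exposed; the builder presets satisfy the stricter
  raw reading (≥10 ΔE₀₀) by starting at L* = 12 with blue chroma.
* the same statistics after simulating each color-vision deficiency.

### Color-vision deficiency model

No specific simulation model is mandated by the consensus language, so
one had to be chosen and documented: the Machado et al.
severity-parameterized matrices (as shipped by the `colorspace` package),
applied in *linear* RGB, with linear interpolation between the published
0.1-severity steps; severity 0 is the exact identity. Achromatopsia,
which has no Machado matrix, is modeled as severity-interpolated
projection onto the neutral axis at equal relative luminance. Two
consequences of this choice are worth knowing. First, the Machado
matrices are not projections, so simulating an already-simulated image
moves colors again — "severity 1" is a model of dichromat *perception*,
not an idempotent gamut reduction. Second, the full-color ΔE₀₀ steps of
an equalized colorful map are *not* uniform after simulation (their CV
rises to roughly 0.2–0.3 for the presets): equalization spends contrast
partly on red–green differences that a dichromat cannot see. The
CVD-safety property the package asserts in its tests is therefore the
one the consensus language actually demands — the luminance component
stays strictly monotone and local contrast never collapses — while the
full simulated statistics are reported for inspection.

## Value-to-color scaling

`value_to_position()` maps a value to `[0, 1]`: linearly, or through the
logarithm-processed form

$$p(v) = \frac{\log(v+f) - \log(v_{\min}+f)}{\log(v_{\max}+f) - \log(v_{\min}+f)}$$

with floor `f = log_floor`. The logarithmic display makes equal value
*ratios* equally conspicuous, which matches how relaxation differences
are usually meaningful (20 vs 30 ms should read like 200 vs 300 ms). Two
deliberate properties:

* **The data are never transformed.** Only the colormap lookup is
  reparameterized; a readback of the source grid after rendering is
  bit-identical. This is asserted in the tests.
* **The floor.** A pure logarithm is undefined at 0, so a small positive
  floor keeps the mapping defined down to v → 0⁺. The default
  `f = vmax/10⁴` is an assumption of this package: it is vanishingly
  small inside typical windows (the worst-case position shift across a
  400–2000 ms window is below 10⁻⁴, as the duality check quantifies)
  while still bounding the mapping. Users reproducing a specific
  published pipeline should set `log_floor` to that pipeline's value.

Quantization to entries is half-open binning `floor(p·n)` with `p = 1`
closing into the top bin; entry ids are 0-based to match 256-row table
conventions. Valid values below the window clamp to entry 0 — never to
black, which is reserved for the sentinel; values above clamp to entry
255.

### The time/rate duality

For a pure log scale, `p(v; a, b) + p(1/v; 1/b, 1/a) = 1` identically, so
a rate map on the reciprocal window with the *inverted* colormap renders
the same image as the time map. `verify_reciprocal_duality()` reports the
worst-case position discrepancy (0 at `log_floor = 0`, small but nonzero
with the default floor), and the test suite additionally checks the
rendered-image version on a phantom at a per-pixel ΔE₀₀ ≤ 1 tolerance —
the slack absorbs the floor perturbation plus one quantization step.
Because orientation is a genuinely open convention, rate kinds default to
the inverted time map at the CLI but `--no-invert` is available.

## Rendering rules

* The sentinel (0 or NaN — NaN is treated as 0, which covers masked
  NIfTI exports) renders exactly `(0,0,0)`. Black was chosen as the
  invalidity color over white because it glares less on the dark
  backgrounds relaxometry images are read on, and over any hue because a
  hue could be confused with a valid color by a color-impaired reader.
* Every default export composes the map with a color bar carrying tick
  numbers and a units label; omitting the bar requires an explicit
  opt-out. In the recommended style, ticks sit at
  `value_to_position(tick)`, so on a log display round numbers appear at
  their true perceptual positions; a legacy linear-label style exists for
  comparison figures. Default ticks are the round numbers
  {1, 2, 5}×10ᵏ inside the window with the endpoints forced — a policy
  default, not a fixed rule.
* Tick and unit text is drawn with a small embedded 5×7 bitmap font so
  rasters are bit-identical across systems; rendering determinism is
  asserted in the tests.

## Synthetic phantoms

`generate_phantom()` rasterizes disks, annuli and rectangles of known
relaxation value onto a sentinel background, with optional Gaussian noise
truncated at zero (relaxation values are physical, so negative samples
are redrawn). Presets sketch a brain-T1-like scene (white matter ≈850 ms,
gray matter ≈1400 ms, CSF ≈4000 ms at 3 T magnitudes) and a
cartilage-T2-like scene (≈35/60 ms); these values are illustrative
inputs, never asserted ground truth. What the phantoms emulate is the
*display* problem — valid regions, sentinel background, plausible value
ranges, noise texture. What they do not emulate: MR signal formation,
partial-volume edges, fitting artifacts, spatially correlated noise.
Passing tests on phantoms therefore validate the mapping and rendering
rules, not the clinical appearance of real maps.

## Numerical choices and problem sizes

* Dense path: 4096 samples; output: 256 entries; equalization tolerance
  CV ≤ 0.01, cap 50 iterations.
* Conversion round-trip is verified on a 17³ sRGB grid at ≤1/255 per
  channel; CIEDE2000 against the 34 published reference pairs at ≤10⁻⁴.
* Property tests use 10⁴ random Lab pairs for metric properties and
  64×64 phantoms for image-level checks — sizes at which every suite
  runs in well under a minute while estimates are stable.
* The equalization oracle (neutral-axis case) inverts the cumulative
  ΔE₀₀ arc length on a 20001-point grid; builder output must agree
  within 0.2 L*.

## Known limitations

* The shipped `lipari-like` / `navia-like` presets approximate the look
  of the published relaxometry colormaps from five anchors each; they
  are not the published tables, whose exact RGB values are defined in an
  external deposit and can be loaded with `read_colormap()` for exact
  cross-checks.
* Perceptual linearity is guaranteed only for a standard sRGB display;
  real displays differ in calibration and viewing-angle behavior, which
  no software-side mapping can fix.
* Anatomy-specific display windows are deliberately absent — ranges are
  always user input.
* Fused displays (color map over grayscale anatomy), DICOM
  presentation-state export and interactive windowing are out of scope.
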