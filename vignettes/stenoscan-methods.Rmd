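---
title: "stenoscan: models, measurement design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stenoscan: models, measurement design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoscan)
```

`stenoscan` quantifies vessel stenosis from an ordered stack of B-mode
ultrasound cross-sections, the acquisition geometry of a probe swept along a
planned path. This vignette documents the models behind each stage, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic validation does and does not demonstrate.

## The quantity of interest

The degree of stenosis compares the residual patent diameter `d` at the
plaque with the vessel diameter `D`:

$$\mathrm{DOS}\% = \left(1 - \frac{d^2}{D^2}\right) \times 100\%.$$

Squaring the diameter ratio makes the measure an area ratio for circular
sections, and makes it unit-free: pixel-space and millimetre-space inputs
agree exactly (`dos()` is tested for this scale invariance). Severity
grading follows the clinical convention: below 30 % mild, 30–50 % moderate
(both boundaries inclusive — the texts defining the bands leave 30 and 50
ambiguous, so the package pins them to the moderate band and tests that
choice), above 50 % severe, the indication for angioplasty.

Whether `d` should be read as a linear plaque-free thickness or as an
area-equivalent diameter is ambiguous in practice; because DOS squares the
ratio, the area-equivalent reading is self-consistent and is the default:
`equivalent_diameters()` converts the shoelace polygon area of each contour
to the diameter of the circle of equal area, $2\sqrt{A/\pi}$.

## The phantom generator

The generator stands in for the scanner hardware and the physical test
objects. A phantom is a straight (or arc) vessel of diameter `D` with a
focal plaque narrowing the lumen to `d`:

* **Design grid.** Nine presets: vessel types A/B/C with `D` = 10/8/5 mm
  crossed with stenosis classes I/II/III, `(d, D)` pairs
  (9, 10), (7.8, 10), (4.5, 10), (7, 8), (6.2, 8), (3.5, 8), (4.5, 5),
  (3.9, 5), (2.2, 5) — the same grid as the bundled
  `phantom_reference_table()`.
* **Plaque profile.** The sources give only `d`, `D` and drawings, so the
  axial lumen profile is a design choice: a cosine taper over a 10 mm
  plaque, symmetric about the phantom midpoint (50 mm of a 100 mm vessel).
  It is smooth, differentiable, and matches the appearance of printed
  phantoms. The plaque is concentric by default; an `eccentricity` option
  offsets the lumen for robustness experiments (DOS, being a diameter
  ratio, is agnostic to concentricity).
* **Rendering.** Echo levels by region — anechoic lumen 0.05, echogenic
  tissue/plaque 0.35, hyperechoic wall 0.85 on a 1.5 mm wall annulus —
  then multiplicative unit-mean gamma speckle (relative SD 0.3), then an
  isotropic Gaussian system blur of σ = 0.1 mm. The blur corresponds to
  the axial resolution of a 7.5 MHz linear probe (FWHM ≈ 0.25 mm); using
  it isotropically is a deliberate simplification (real lateral resolution
  is coarser). Speckle-before-blur is the standard first-order B-mode
  approximation; no wave propagation or point-spread-function physics is
  simulated. Rendering is a pure function of the spec, position, raster and
  seed; frames in a series draw seeds `seed + frame_index`.
* **Raster.** 0.1 mm/px on 256×256 frames: sub-millimetre pixels are
  realistic for a 38 mm probe at shallow depth while keeping frames small.

What the generator does **not** emulate: attenuation and depth-dependent
gain, anisotropic resolution, refraction and reverberation artifacts,
off-axis vessel inclination, wall layering, and motion. Passing the
synthetic studies therefore shows the measurement chain is correct and
noise-robust under this noise model — not that it is ready for clinical
frames.

## Scan-path planning

Both scan methods consume at least three marked sites (arterial
anastomosis, loop, venous anastomosis). The arc path is read as the
classical circumcircle construction: perpendicular bisectors of two chords
through their midpoints meet at the unique center equidistant from the
three sites (`circle_from_points()`, tested to 1e-9 on random triples).
Collinear sites (triangle area below tolerance) raise a degenerate-geometry
error that points to the linear method. Waypoints are laid out at the
requested slice spacing along the arc from the first to the last site, in
the direction that traverses the middle site; `theta` is the polar angle
about the center, so consecutive frames differ by `spacing / radius`
radians. Linear plans interpolate the polyline with `theta = 0`.

The native capture spacing is `speed / frame_rate` (5 mm at 0.5 cm/s and
1 Hz). Plans requesting larger spacing are flagged `needs_interpolation`;
the 3D stage inserts interpolated sections so no gap exceeds the
interpolation spacing (default 20 mm). Workspace-limit violations warn
rather than fail, since no hardware is driven.

## Segmentation

### The snake

Boundaries are delineated by a greedy active-contour model. The contour
`v(s)` (closed, uniformly parameterized, counter-clockwise) minimizes

$$E_\mathrm{snake} = \int_0^1 E_\mathrm{int}(v(s)) + E_\mathrm{ext}(v(s))\,ds,$$

with internal energy
$E_\mathrm{int} = \alpha |v'|^2 + \beta |v''|^2$
(cyclic finite differences, mean over vertices), external energy
$E_\mathrm{image} + E_\mathrm{con}$ with the constraint term fixed at zero,
and image energy
$E_\mathrm{image} = \omega_\mathrm{line} E_\mathrm{line} +
\omega_\mathrm{edge} E_\mathrm{edge} + \omega_\mathrm{term} E_\mathrm{term}$
where `E_line` is the smoothed intensity, `E_edge` the negative squared
gradient magnitude and `E_term` the curvature of level lines of an
extra-smoothed copy (2 px by default; curvature is noise-sensitive).

Numerical choices, all covered by tests:

* **Minimizer.** Deterministic greedy sweeps: vertices are visited in index
  order and moved to the lowest-energy position in their
  `(2·search_radius + 1)²` neighborhood, counting every energy term the
  vertex participates in. Ties prefer the smallest displacement, then
  row-major neighborhood order. Greedy sweeps never increase the total
  energy; the contour is resampled to uniform arc length after each sweep
  unless resampling would raise the energy, so the recorded energy trace is
  non-increasing, and at convergence (zero move tolerance) no single-vertex
  move in the neighborhood improves a brute-force recomputation of the
  total energy.
* **Field normalization.** Each image field is scaled to unit maximum
  magnitude before weighting (`normalize = TRUE`). The raw squared-gradient
  field of a unit-intensity image has magnitude ~0.04, which the elastic
  term would crush at any useful `alpha`; normalization makes the weights
  dimensionless, the established practice for greedy snakes. The raw
  fields remain available (`normalize = FALSE`), where the combined field
  with weights (0, 1, 0) equals `E_edge` exactly.
* **Sampling.** Image energies are sampled at vertex positions by bilinear
  interpolation; out-of-domain samples clamp to the border and are flagged
  in the energy breakdown. Pixel centers sit at integer coordinates,
  origin top-left, y down; serialized contours carry this convention.
* **Defaults.** `alpha` 0.1, `beta` 0.4, weights (0, 1, 0.3),
  `search_radius` 2 px, 64 vertices, `move_tolerance` 0.05, at most 200
  sweeps. No reference values exist for these; they are recorded in every
  report and overridable. One consequence of the stiffness term worth
  knowing: a snake with `beta > 0` cannot *deflate* a circle through
  single-vertex moves (any lone deviation is penalized), so capture-range
  tests use `beta = 0` and practical initialization is handled below.

### Initialization and sub-pixel measurement

A greedy pixel-grid snake is a local refiner; it neither finds the vessel
from afar nor resolves structures at the scale of the system blur. Two
radial-profile stages bracket it in `segment_frame()`:

1. **Initialization.** From a seed inside the lumen, intensity profiles are
   cast along 48 rays and averaged over an 11-ray angular sector
   (exploiting local circularity to suppress speckle without degrading
   radial resolution). Each averaged profile, up to the wall crest, is fit
   with a **double-step edge model**
   $v(r) = L + (P - L)\,\Phi((r - r_1)/s) + (W - P)\,\Phi((r - r_2)/s)$:
   levels solved by ridge-stabilized linear least squares inside a bounded
   quasi-Newton search over the edge positions and blur width, started
   from derivative peaks. `r_1` is the lumen boundary, `r_2` the
   plaque–wall interface (the vessel diameter). When the inner step
   amplitude falls below 12 % of the total rise the two edges are merged —
   the slice has no resolvable plaque and `d = D`. Per-ray radii are
   cleaned by a circular median filter; the lumen (expanded from the seed)
   and vessel (shrunk onto the wall interface) polygons initialize the two
   snakes.
2. **Measurement.** After snake convergence the radii are re-measured
   around the converged lumen centroid (skipped when the centroid moved
   less than half a pixel), and the final contours are built from the
   fitted sub-pixel radii, with the lumen clipped inside the vessel.

The double-step fit is the component that resolves class-I plaques: a
0.25–0.5 mm bright ring under a 0.1 mm-σ blur leaves the lumen edge as a
gradient *shoulder* rather than a separate peak, so derivative-peak
detectors (and the snake itself) merge it with the wall edge; the
parametric fit separates the two edges below the classical resolution
limit. Sequential propagation (`propagate_series()`) warm-starts each frame
from the previous converged lumen centroid, keeps results independent of
later frames, and on failure raises an error naming the frame while
returning the earlier results in the condition.

## 3D reconstruction

Each contour is scaled to mm about the frame center and oriented by its
frame's rotation angle `theta` about the scan axis using the clockwise
convention `x' = x cosθ + y sinθ`, `y' = y cosθ − x sinθ`, `z' = z` — the
convention is pinned by a round-trip test at 1e-9. Linear plans stack
frames perpendicular to the path; circle plans sweep the image plane about
the arm axis, so the in-plane lateral coordinate is radial (offset by the
arc radius) and image depth maps to the world vertical — reconstructed
section centroids then lie on the plan's arc, which is tested. Between
captured sections, vertices, angle and position are linearly interpolated
after correspondence resampling (equal vertex counts, cyclic-shift
alignment minimizing summed vertex distance). Adjacent rings are
triangulated and capped, giving closed meshes (Euler characteristic 2,
positive enclosed volume, lumen volume decreasing with design DOS).
Meshes export as ASCII STL and PLY — ASCII on both counts so every artifact
of a run is plain text and diffable.

## The validation studies

* **Reference tables.** The bundled phantom and clinical tables are
  regression fixtures: every DOS cell recomputes from its printed `(d, D)`
  pair and every error cell as an absolute DOS difference, compared at the
  printed 0.1 precision. Ten cells of the printed sources are internally
  inconsistent with the DOS formula (three design-column DOS cells, three
  CBCT DOS cells, two CBCT-vs-scanner error cells, two clinical error
  cells); `validate_table_fixtures()` reports exactly these as documented
  exceptions rather than silently tolerating them.
* **Agreement.** Ordinary least squares of the clinician series on the
  scanner series across the ten patients, `agreement()`, reporting per-pair
  absolute errors and R² (the acceptance suite requires R² > 0.95).
* **Phantom recovery.** `run_phantom_study()` renders all nine presets at
  default noise (seeds derived from a master seed), runs the full
  segmentation-to-report pipeline on a 9-frame linear scan spanning
  30–70 mm at the native 5 mm spacing (frame at the plaque center
  included), and compares the recovered maximal DOS with the design value.
  The acceptance suite requires the maximum absolute error over the nine
  presets to stay within 3 percentage points, and the recovered severity
  class to match the design class for all nine. These problem sizes — 81
  frames of 256×256 px per study — keep a full run in the low minutes on
  one core.

## Known limitations

* The noise model omits the artifacts listed above; accuracy on clinical
  frames is untested by construction.
* The vessel is assumed approximately convex and star-shaped about the
  seed (radial parameterization); dissections or highly eccentric slices
  would need the snake output without the radial measurement stage.
* Greedy snakes with stiffness cannot deflate large initialization errors;
  segmentation quality rests on the radial initialization finding the
  vessel, which needs the seed inside the lumen.
* Circle-plan reconstruction assumes the sites are roughly coplanar; the
  plan stores one mean height.
* The double-step fit assumes one plaque interface per ray inside the
  wall crest; multi-layered walls would bias `r_2`.
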