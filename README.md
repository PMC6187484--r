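# stenoscan

Quantification of arteriovenous-fistula (AVF) stenosis from sequential
B-mode ultrasound cross-sections, with a fully synthetic, ground-truthed
phantom bench for validating the whole measurement chain.

Hemodialysis patients depend on a patent AVF; its narrowing is graded by the
**degree of stenosis**

> DOS% = (1 − d² / D²) × 100

where *D* is the vessel diameter and *d* the residual patent diameter at the
plaque. Scanning an AVF by hand is slow and operator-dependent; a robotic
scanner sweeping the probe along a planned path produces an ordered stack of
cross-section frames that can be segmented, reconstructed in 3D and graded
automatically. `stenoscan` implements that computational chain for R users:

* **Phantom simulation** — parametric stenosed-vessel phantoms (vessel types
  A/B/C with D = 10/8/5 mm, stenosis classes I/II/III near 20/40/80 % DOS),
  rendered as B-mode-like frames: anechoic lumen, echogenic wall,
  multiplicative gamma speckle, Gaussian system blur. Every frame carries its
  ground-truth masks.
* **Scan-path planning** — circle scans through the marked arterial (A),
  loop (L) and venous (V) sites via the circumscribed-circle construction,
  or linear scans along a polyline; per-frame rotation angles and slice
  spacing are derived from probe speed and frame rate.
* **Segmentation** — greedy active-contour model (snake) minimizing
  elasticity/stiffness internal energy plus intensity/edge/curvature image
  energy, initialized and sharpened by sector-averaged radial profiles with
  a parametric double-step edge fit for sub-pixel lumen and wall-interface
  radii.
* **3D reconstruction** — per-frame contours rotated about the scan axis,
  linearly interpolated between captured slices, meshed into closed lumen
  and vessel surfaces (ASCII STL/PLY export).
* **Stenosis reporting** — per-slice DOS, maximal stenosis location,
  mild / moderate / severe grading (<30 %, 30–50 %, >50 %), and agreement
  statistics (absolute differences, OLS R²) between two measurement series.

## Worked example

Render a severe-stenosis phantom (type C, class III: d = 2.2 mm, D = 5 mm),
scan it at the native 5 mm slice spacing, segment the series and grade it:

```r
library(stenoscan)

spec <- make_phantom_spec("C", "III")
plan <- build_plan(list(c(0, 0, 40), c(0, 0, 50), c(0, 0, 60)),
                   method = "linear", slice_spacing = 5)
series <- generate_series(spec, plan, noise_params(seed = 42))
segs <- propagate_series(series$frames, first_seed = c(128.5, 128.5))

slices <- do.call(rbind, lapply(seq_along(segs), function(k) {
  dd <- equivalent_diameters(segs[[k]]$lumen, segs[[k]]$vessel, 0.1)
  data.frame(frame_index = k - 1L,
             axial_position = series$frames[[k]]$axial_position,
             d = dd[["d"]], D = dd[["D"]])
}))
series_report(slices, provenance = "C-III")
```

```
  frame_index axial_position    d    D
1           0              0 4.91 5.03
2           1              5 5.01 5.02
3           2             10 2.18 5.01
4           3             15 4.92 5.04
5           4             20 4.97 5.01
<stenosis_report> 5 slices; max DOS 81.0% at 10.0 mm (severe stenosis)
```

The slice 10 mm into the scan is the plaque center: the recovered residual
diameter 2.18 mm against a vessel of 5.01 mm gives DOS 81.0 %, within one
percentage point of the 80.6 % design value, and the phantom is correctly
graded severe. Away from the plaque the lumen fills the vessel (d ≈ D,
DOS ≈ 0).

Agreement between the bundled scanner and clinician DOS series:

```r
cl <- clinical_reference_table()
agreement(cl$rus_dos, cl$doc_dos)
#> <agreement_stats> n = 10: mean |error| 4.05 pp, max 9.30 pp, R^2 = 0.986
```

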