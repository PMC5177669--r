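---
title: "Methods: virtual trajectories, craniometry and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual trajectories, craniometry and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ozaplan)
```

## The model

Access to a basilar apex (BX) aneurysm passes over the internal carotid
artery, so the usable line of sight is pinned by two anatomical points: the
basilar artery apex **A** and the ICA bifurcation **B**. `ozaplan` treats
the surgical corridor as the ray

$$ \mathbf{p}(t) = \mathbf{A} + t\,\frac{\mathbf{B}-\mathbf{A}}{\lVert\mathbf{B}-\mathbf{A}\rVert}, \qquad t \ge 0\ \text{(mm)}, $$

and defines **C** as the exit of this ray through the outer cranial
surface. Because the bifurcation is anchored by perforators, the corridor
cannot be tilted above B; C therefore marks the centre of the cranial
window an approach must provide. Two chord distances summarise how invasive
that window is: C to the zygomatic arch (C–Z) and C to the lateral canthus
(C–L). Small distances mean the window encroaches on the zygoma / orbital
rim, i.e. an orbitozygomatic approach (OZA); the packaged decision rule
recommends the OZA when both are below 30 mm, calls a standard pterional
craniotomy sufficient when both exceed 40 mm, and labels everything else
(including values exactly on a threshold) indeterminate. The 30/40 mm band
is deliberate: a real mid-band case exists in the packaged five-patient
table in which pterional clipping was attempted and failed.

All coordinates live in a right-handed frame at the dorsum sellae apex
(+x lateral, +y anterior, +z superior; midsagittal plane x = 0), so
"height" is a signed z and "width" is |x|. Heights are *not* floored at
zero — the published ranges extend to −5 mm (apex) and −1.4 mm
(bifurcation).

## Geometry implementation

* **Ray casting.** Möller–Trumbore intersection against every triangle,
  vectorised; the exit is the *largest* forward parameter, which on a
  thin-shelled skull selects the outer table. Whether the reference
  surface-rendering workstations report the inner or outer table is not
  documented; the outer table is assumed. Grazing hits (barycentric
  coordinate within 1e−12 of an edge) are resolved deterministically by
  nudging the origin 1e−6 mm along the ray and re-casting.
* **Tolerances.** Collinearity of C with the A–B line is checked through
  the perpendicular-component norm (cancellation-safe) at 1e−6 mm;
  on-surface placement at 1e−3 mm; mesh-versus-analytic agreement at
  0.5 mm. The three scales separate algorithmic error (first two) from mesh
  discretisation error (last): at the default icosphere subdivision (4;
  5120 faces) the measured discretisation error is below 0.2 mm.
* **Oracle.** For ellipsoid phantoms the exit parameter has a closed form
  (positive root of the ray–ellipsoid quadratic),
  `analytic_ellipsoid_intersection()`; the test suite and acceptance
  script compare the mesh path against it over random interior pairs.
* **C–Z reference.** The arch can be treated as a polyline (default;
  minimum distance over clamped segment projections) or as its mid-arch
  point (`cz_mode = "midpoint"`). Published descriptions use both; the
  polyline is the default because the figure annotations measure to the
  arch as a line, and the midpoint distance is never smaller, so the
  default is the conservative (OZA-leaning) choice. Distances are 3-D
  chords, not scalp geodesics — the measurement method on clinical
  workstations is unstated and chords are the reproducible option.

## The synthetic cohort

No raw imaging cohort can be shipped, so the generator builds the study
conditions in code:

* **Skull.** A triangulated ellipsoid, semi-axes 70 × 90 × 65 mm (lateral ×
  AP × SI), centred 20 mm above the dorsum sellae so the frame origin sits
  in the skull-base region. Any convex closed surface preserves the
  qualitative trajectory geometry; the semi-axes, centre height and mesh
  resolution are parameters.
* **Landmarks** are placed at fixed unit-sphere directions and scaled with
  the semi-axes, so they lie exactly on the analytic surface for any skull
  size and mirror across x = 0 to machine precision. The external auditory
  canal sits low-lateral (z = −25 mm at default scale), the five-point
  zygomatic arch polyline runs posterior → anterior just above it
  (z = −20 mm), and the lateral canthus sits anterolateral at orbital level
  (y = 70, z = 0 mm). These placements are anatomy-shaped choices, not
  measured values.
* **Vascular points.** Heights of A and B and width of B are drawn from
  truncated normals calibrated to the published cohort (4.9 ± 3.8 mm in
  [−5, 10.5]; 5.7 ± 3.1 mm in [−1.4, 15]; 15.7 ± 3.4 mm in [8.4, 35.1]).
  Truncating a normal parameterised directly by the published mean/SD at an
  asymmetric range shifts its realised mean (for the apex height, by about
  −0.5 mm); the generator instead *moment-matches*: it solves for the
  underlying (μ, σ) whose truncated distribution has exactly the published
  mean and SD (`fit_truncated_normal()`, deterministic Nelder–Mead on the
  closed-form truncated moments; draws by inverse-CDF, so every draw
  respects the range). The anteroposterior positions of A and B are not
  published; defaults place A 8 mm posterior and B 10 mm anterior to the
  dorsum sellae (approximating interpeduncular vs supraclinoid positions)
  with 2 mm Gaussian jitter, all configurable. A is near-midline
  (|x| ≤ 2 mm). The 80 default samples are two sides of 40 subjects,
  treated as independent draws; `mirror_sides = TRUE` duplicates subjects
  across hemispheres instead. Every point is verified to lie strictly
  inside the mesh (parity ray-casting), with resampling and a named error
  after 25 failures.
* **Voxel path.** The optional CT-phantom route rasterises the mesh by
  column-parity fill and re-extracts a cuberille surface (boundary voxel
  faces). Its deviation is bounded by about half a voxel diagonal
  (≈ 0.87 × spacing), within the 2 × spacing contract checked in the
  tests; Hausdorff distances are estimated on evenly strided vertex
  samples. Supported spacings are 0.25–2 mm.

What the phantom does *not* emulate: real cranial shape (temporal fossa,
orbital rims, inner/outer tables), vessel curvature, brain and neural
structures that further limit a real operative field, and measurement error
of a human operator on a workstation. Passing tests therefore demonstrate
the correctness and calibration of the computational chain and the
*direction* of the anatomy–distance relationships, not clinical
reproduction of the published correlation coefficients — the published
per-pair r values came from 80 real anatomies that are not available, and
they are intentionally not targets. The packaged five-patient table is the
only real data in the package, and the decision rule is checked against its
recorded operative approaches.

## Statistics

Pearson r with two-sided p-values from the t distribution on n − 2 degrees
of freedom (`stats::cor.test`), six (outcome × predictor) pairs, flagged at
the Bonferroni-corrected level α = 0.05/3 ≈ 0.0167 (reported as 0.017 to
three decimals, the convention used in the source analyses). m = 3 counts
the three anatomical predictors per distance family and is configurable.
Sidedness is not documented in the source; two-sided is assumed (the
conservative choice). Cohorts of n = 2 run end-to-end but the pipeline
warns and reports r without p. Zero-variance columns raise an error naming
the column rather than returning NaN.

## Reproducibility and problem sizes

Every generator is a pure function of (parameters, seed); `run_pipeline()`
writes a JSON manifest (config + seed + package version) from which a rerun
reproduces all numeric artifacts byte-for-byte (the PNG scatter is excluded
from the byte contract — raster metadata is not numeric output). The test
and acceptance runs use the default 5120-face skull; distribution checks
use n = 2000–5000 draws, the oracle sweep 1000 random trajectories, and the
sign-recovery check 20 cohorts of n = 80 — sizes chosen so the full suite
completes in about a minute on a laptop while keeping Monte-Carlo standard
errors well inside the asserted tolerances.

## Known limitations

* The ellipsoid skull makes C-to-landmark distances systematically shorter
  in the anterolateral direction than on a real cranium with a temporal
  fossa; absolute C–Z/C–L magnitudes from the phantom should not be read
  clinically.
* The cuberille surface is not guaranteed two-manifold at staircase
  corners; it satisfies distance bounds, not topological ones.
* The decision thresholds encode the published 3 cm / 4 cm observations
  from five patients; they are defaults, not validated cutoffs.
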