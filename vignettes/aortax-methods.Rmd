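---
title: "Methods: post-segmentation aortic morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-segmentation aortic morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, parameters and numerical choices behind
`aortax`, in the spirit of a methods section: what each stage computes, why
the defaults are what they are, and what the phantom-based tests do and do
not demonstrate about real data.

## Inputs and conventions

The pipeline consumes a CT angiography volume in Hounsfield units and an
aligned integer label map containing the aorta plus the organs used by the
landmark rules (left/right ventricular blood pools, liver, kidneys, the
three arch branches, the common iliac arteries). Structure names follow the
TotalSegmentator convention so real segmentations drop in unchanged; the
network inference itself is out of scope — label maps are inputs.

All volumes are reoriented on read to a fixed anatomical convention (array
axes run left-right, posterior-anterior, inferior-superior), because the
landmark rules speak of "most superior" and "above/below". All geometry
downstream is in physical millimetres; voxel indices appear only inside the
rasterization and resampling kernels, since CTA voxels are routinely
anisotropic.

## Lumen refinement and calcification

The upstream aorta label includes the vessel wall, calcified plaque and any
mural thrombus, while clinical diameters are read on the contrast-enhanced
lumen. The refinement therefore re-splits the label using its own HU
statistics:

* the label is thinned to a 3-D curve skeleton (topology-preserving
  thinning, anchored on the ridge of the distance transform so symmetric
  tubes do not collapse), dilated by 1 mm, and the HU values of the
  surviving voxels give the lumen mean $\mu$ and spread $\sigma$;
* the lumen is the set of aorta voxels with HU in
  $[\mu - 5\sigma,\; \mu + 3\sigma]$ — asymmetric because the wall is much
  darker and calcium much brighter than blood — restricted to connected
  components touching the dilated skeleton, then cleaned by morphological
  opening and closing and by filling enclosed cavities ("removing holes and
  outliers"). A zero-$\sigma$ band (constant-intensity input) is widened to
  $\pm 1$ HU. Voxels at or above the calcification threshold are never
  re-admitted by the closing;
* calcified plaque is every aorta voxel outside the lumen with HU at or
  above the adaptive threshold $\max(v_\text{minhu}, \mu + \alpha\sigma)$,
  defaults $v_\text{minhu} = 400$ HU and $\alpha = 3$. With typical
  contrast (e.g. $\mu = 300$, $\sigma = 20$) the floor dominates:
  $\max(400, 360) = 400$ HU.

Choices the protocol leaves open, decided here:

* **Calcification-ratio denominator.** The ratio is reported as
  $100\,|\text{calc}| / (|\text{lumen}| + |\text{calc}|)$ — the calcified
  share of the reconstructed vessel content. It is configurable.
* **Morphology radii.** Opening and closing use a metric ball of one
  in-plane voxel — the smallest element that removes single-voxel noise.
* **Component rule.** Components intersecting the dilated skeleton are
  kept, rather than the single largest, because two-part cardiac scans
  legitimately contain two aortic pieces.

## Centerline and frames

The centerline is a minimal-cost path over the in-lumen voxel graph
(26-connectivity) with edge cost $\ell / (\varepsilon + d)$, where $\ell$
is the step length and $d$ the distance from the target voxel to the lumen
boundary ($\varepsilon = 0.1$ mm). Wide, central voxels are cheap, so the
path tracks the centers of maximally inscribed spheres without requiring an
external vascular-modelling dependency. Endpoints depend on the scan class:
full scans run from the iliac bifurcation (most superior point where both
dilated iliac labels meet the aorta) to the left-ventricle junction (center
of mass of the dilated-LV/dilated-lumen overlap); abdominal scans end where
the lumen crosses the superior scan boundary; two-part cardiac scans get
one centerline per component.

The discrete path carries voxel staircase and, at bends, can sit up to a
voxel off-axis because the distance-to-boundary plateau is
quantization-flat. Three numerical steps handle this:

1. a cubic smoothing spline per coordinate against cumulative chord length,
   with flexibility fixed at 0.3 degrees of freedom per mm (anatomy above
   roughly 7 mm wavelength is preserved; staircase is suppressed). The
   path's first and last couple of voxels are endpoint-snap artifacts and
   are trimmed before fitting;
2. two recentering passes: each sample moves to the center of mass of its
   orthogonal lumen cross-section (slices that look tilted or cap-cut —
   area outside 0.6–1.4 times the median — are left alone, and shifts are
   capped at 3 mm), each followed by a refit whose smoothness is chosen by
   generalized cross-validation (capped at 0.6 df/mm) since the residual
   noise is then small and uncorrelated. The second pass corrects the
   off-axis bias at bends that the first pass measured in slightly tilted
   planes;
3. extension of the fitted curve to the lumen surface — after dropping the
   fit's own boundary samples, which carry the largest variance — along a
   variance-reduced end direction (the averaged tangent of the outermost
   samples, continued by the local curvature when it is estimated above
   1/100 mm$^{-1}$), so arc lengths cover the full vessel. Ends farther
   than 25 mm from the surface are genuine interior points and are not
   extended.

Samples sit on a uniform 1 mm arc-length grid, with the final sample placed
at the true end so coverage is not truncated while the slice count stays
`floor(length/step) + 1`.

Local frames start from an up-vector (anterior by default, lateral
fallback) orthogonalized against the first tangent and propagate by the
rotation-minimizing double-reflection scheme, which avoids the instability
of the naive Frenet frame at inflections; the consecutive-normal dot
product is checked and a negative value flips the normal (and binormal).

## Curved planar reformatting

Each centerline sample spans a plane via its normal/binormal; grid point
$(u, v)$ maps to $c + u\,\mathbf{n} + v\,\mathbf{b}$. HU values are sampled
trilinearly; the lumen mask is sampled as a trilinearly interpolated
indicator thresholded at 0.5 — still binary per slice, but with sub-voxel
boundary placement (plain nearest-neighbor sampling inflates the lumen by
about a quarter voxel, a measurable diameter bias). Defaults: 1 mm slice
step, 0.5 mm in-plane resolution, 40 mm half-width. At strong bends the
orthogonal plane can re-intersect an adjacent limb of the vessel; each
slice therefore keeps only the in-plane connected component around the
centerline point. Plane self-intersection at extreme curvature is not
corrected; affected slices are expected to fail the downstream ellipse
aspect check.

## Landmarks and segments

Arc length runs from 0 at the iliac bifurcation toward the valve, so
"distal" (away from the heart) means decreasing arc length. Landmarks:

* *ventricular-aortic junction*: organ-overlap rule (dilate LV and lumen by
  5 mm, center of mass of the intersection, nearest centerline sample).
  The same 5 mm radius is reused for the LV overlap as for the arch
  arteries, where it is prescribed;
* *proximal arch*: overlap with the brachiocephalic trunk; *distal arch*:
  the left-subclavian projection shifted 20 mm along arc length toward the
  descending aorta (arc length being the natural metric on a curve),
  clamped with a warning at the centerline end. The left common carotid is
  detected and reported but drives no downstream rule;
* *diaphragm*: alternating closest-point iteration between the
  right-ventricle and liver surfaces starting at the most inferior RV
  point; the midpoint of the converged pair is projected onto the
  centerline;
* *renal*: the centerline point closest to the line through the two kidney
  centers of mass;
* *aortic root*: on the cross-sectional-area profile, the sinus of
  Valsalva is the maximum within 20 mm distal of the junction (window
  half-open: the junction sample itself is not a candidate), the
  sinotubular junction the minimum 5–25 mm beyond the sinus, and the
  annulus the minimum within 10 mm proximal of the junction along the
  combined LV-aorta centerline. That combined line is built by continuing
  the medial path from the valve end into the LV blood pool (toward its
  center of mass, up to 30 mm) — the construction the protocol requires but
  does not detail. Ties break toward the window start.

Segment boundaries equal landmark arc lengths exactly: infrarenal
[0, renal], suprarenal [renal, diaphragm], descending [diaphragm, distal
arch], arch [distal, proximal arch], ascending [proximal arch, junction].
Missing landmarks flag the affected segments unavailable — never silently
merged.

## Biomarkers and quality control

The per-segment measurement slice is the largest cross-sectional area
within the segment (smallest for the sinotubular junction and annulus;
ties to the lower arc length). The maximal diameter is the longest chord
through the section's center of mass over 1° ray directions, with sub-pixel
boundary crossings by linear interpolation along each ray; a short circular
median (±2°) over the chord-versus-angle curve suppresses single-angle
spikes from resampled-boundary jag without affecting smooth sections.
Crescent-shaped sections whose center of mass falls outside the mask are
flagged degenerate and fail QC.

Tortuosity is centerline length over the Euclidean distance between the
anchor landmarks (≥ 1 up to rounding): distal arch to diaphragm for the
descending index, bifurcation to ventricular-aortic junction for the
full-aortic index.

Safeguards: the field-of-view classifier counts aorta components
(ignoring fragments below 1 cm³) and checks which ancillary labels the
dilated aorta reaches; the surface-to-volume ratio of the *raw thresholded*
lumen — before the cosmetic morphology, which would mask exactly the
porosity being screened for — rejects non-contrast or artifact-ridden scans
above 0.5 mm⁻¹; and each measured slice must keep its best-fit-ellipse
aspect ratio (square root of the second-moment eigenvalue ratio) at or
below 2.5. The two scalar QC thresholds are calibration choices on the
phantoms, not protocol values. Surface area is estimated with the co-area
formula — the integral of the gradient magnitude of the mask indicator,
lightly smoothed (σ = 0.3 voxel) to regularize the discrete gradient —
because the QC needs a scalar area, not a mesh; it reproduces the analytic
sphere to within ten percent while retaining the porosity signal that
heavier smoothing would average away.

Agreement statistics against manual readings (MAE, MAPE, bias, Pearson r,
coefficient of variation, Bland–Altman limits bias ± 1.96·SD) use the
signed per-pair difference over the per-pair average for the CV; an
absolute-value variant is available behind a flag since conventions differ.

## The phantom generator

The generator is the package's study-conditions module, not a test
convenience: its defaults define the conditions every claim is evaluated
under. A full-aorta phantom is a tube (lumen radius 10 mm, wall 2 mm)
following an analytic C1 curve — abdominal and thoracic runs of 100 mm
each, a semicircular arch of radius 30 mm, a 60 mm ascending run — with a
contrast-blood HU model N(300, 20), wall ≈ 50 HU, soft-tissue background,
calcified blobs at ≥ 700 HU placed on the lumen/wall interface until a
target volume fraction is met, and an organ layout (LV/RV, liver, kidneys,
three arch branches, two iliacs) that makes every landmark rule fire. The
descending run carries a gentle two-bump lateral bow (default amplitude
10 mm) whose curvature radius stays well above the lumen radius — tortuous
the way aging aortas are tortuous, through long-wavelength bowing rather
than kinks — and whose displacement and slope vanish at the diaphragm level
so the landmark constructions stay unbiased. Root features add a +3 mm
sinus bulge 10 mm from the valve and a −1.5 mm sinotubular narrowing at
24 mm. Default voxel spacing is 1 mm isotropic; the straight/semicircular
tubes used for the tortuosity checks are generated at 0.8 mm.

Ground truth is computed from the analytic curve (arc-length
parameterization established by dense quadrature, accurate well below
0.1%): landmark arc lengths at the constructed junctions, tortuosity
indices from the curve itself, the exact lumen mask (center-point
inclusion, distances refined against the analytic curve so the tube is not
quantization-fattened), and the realized calcified fraction. For the
bifurcation the constructed truth is the junction rule applied to the exact
masks, since the rule's ideal output sits a few millimetres above the
geometric apex by design. Restricted fields of view are produced by
cropping (a cardiac crop leaves two disconnected aortic components); the
non-contrast phantom sets blood HU equal to the wall and injects heavy
salt-and-pepper outliers into the peripheral half of the cross-section,
emulating the partial-volume and streak artifacts of unenhanced boundaries
while the vessel core — which the skeleton samples — stays representative.

What the phantom does *not* emulate: realistic texture and noise
correlation, beam hardening, motion/ECG artifacts, dissection membranes,
mural thrombus with near-blood attenuation, and anatomical variation in
organ shape. Passing phantom tests therefore demonstrates the geometric
and statistical machinery (segmentation refinement, centerline accuracy,
landmark logic, measurement calibration, QC wiring) under controlled
conditions, not clinical performance.

## Problem sizes and determinism

The bundled tests and the acceptance script run full analyses on ~100×100×
300-voxel phantoms at 1 mm (tens of seconds each on one core), tube
phantoms at 0.8 mm for the tortuosity checks, and a coarser 1.5 mm batch
for the parallel-determinism check; landmark recovery is evaluated across
ten seeded phantoms. All randomness is confined to the generator's seed;
the analysis itself is deterministic, so identical inputs and configuration
produce byte-identical JSON reports, including under forked parallel batch
execution.

## Known limitations

* The medial path inherits voxel quantization; despite spline smoothing
  and recentering, tortuosity indices carry residual error of order 0.01
  on tight curvature (bend radius approaching the lumen radius), and
  oblique-plane effects can inflate diameters by a few tenths of a
  millimetre near strong bends.
* The annulus search depends on the combined LV-aorta centerline; when the
  LV blood pool is missing or does not meet the lumen, the annulus (and on
  cardiac scans the root landmarks) are reported missing rather than
  guessed.
* The calcification ratio counts voxels, not calcium mass; no
  Agatston-style scoring is attempted.
* DICOM ingestion, the upstream segmentation network, cohort-level
  statistics and rendering-heavy visualization are out of scope.
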