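---
title: "Measuring single-nephron GFR and glomerular morphometry from intravital multiphoton imaging"
author: "nephroflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-nephron GFR and glomerular morphometry from intravital multiphoton imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Intravital two-photon microscopy of the superficial kidney cortex makes two
hemodynamic quantities of a single nephron directly observable:

1. **Single-nephron glomerular filtration rate (snGFR)**. A freely filtered
   fluorescent tracer (a Lucifer-Yellow analogue) injected into the tail
   vein appears in the glomerulus and then advances as a dye front along
   the downstream proximal tubule (PT). If `Q` is the filtration rate
   (µm³/s) and `A(s) = π r(s)²` the luminal cross-section at arc length
   `s`, conservation of volume gives the front velocity `v(s) = Q / A(s)`
   and the arrival time

   `t_arr(s) = t0 + (1/Q) ∫₀ˢ A(u) du`.

   The cumulative luminal volume `V(s) = ∫₀ˢ A(u) du` is therefore *linear*
   in arrival time with slope `Q`. snGFR in nl/min is `Q · 60/10⁶`
   (1 nl/min fills 10⁶ µm³ in 60 s). Tubules shorter than 45 µm of visible
   length are excluded, matching the standard inclusion criterion for this
   preparation; acquisition is single-plane at 6 frames/s.

2. **Arteriole diameter and glomerular volume.** Afferent and efferent
   arterioles (assigned by the annotator from the direction of blood flow —
   a live-imaging judgement the software never attempts) are captured in a
   z-stack (default 1 µm z-step over 120 µm) and measured after 3D
   reconstruction; the glomerular capillary tuft volume is the voxel count
   of its mask times the voxel volume.

The statistical layer mirrors the paired longitudinal design: each nephron
or glomerulus is measured before and after treatment, compared with a
classical paired two-tailed Student t-test; group families use one-way
ANOVA with Šídák-adjusted pairwise comparisons
(`p_adj = 1 − (1 − p)^m`); treatment effects are summarized as percent
change of group means, truncated toward zero when quoted as "~N%".

## Pipeline

```
simulate (synthetic phantoms)  ──►  TIFF + YAML sidecar + ROI JSON
trace_tubule(series, seeds)    ──►  centerline + FWHM radii -> length, volume
extract_traces / front_arrival ──►  t_arr(s) per position
compute_sngfr                  ──►  slope of V(s) ~ t_arr  -> nl/min
reconstruct_vessel             ──►  EDT centerline -> mean diameter
glomerular_volume              ──►  voxel count x voxel volume
summarize_groups / anova_sidak ──►  paired stats, percent change, report
```

All geometry is in physical micrometres. Rasterization samples pixel
centres: 0-based index `i` maps to `(i + 0.5) · pixel_size`. Physical
metadata travels in a YAML sidecar next to each TIFF and is mandatory on
load — there are no silent defaults.

## Tubule tracing (semi-automatic by design)

The user supplies ordered seed clicks from the glomerulotubular junction
outward; the click order defines the flow direction. Automation starts
from there:

- The working image is a maximum-intensity projection over the last 3
  frames, where the tubule is completely filled and contrast is best.
- Each point is snapped to the tubule centre by taking the intensity
  profile perpendicular to the local path direction, locating the interval
  above half of the peak-over-background amplitude (FWHM), and moving the
  point to the interval midpoint (shift capped at the 5 µm search radius).
  Profiles whose halfwidth is an outlier (≥ 1.4× the path median) are
  distrusted — this happens where an oblique profile clips the bright
  glomerulus near the junction — and their lateral shift is interpolated
  from accepted neighbours, which is valid because a click-offset field
  varies smoothly along the path.
- The snapped polyline is resampled at 1 µm, re-snapped with a halved cap,
  smoothed with a short moving average, and resampled again. Per-point
  radius is half the FWHM; unreliable points are flagged and filled by
  interpolation.

The FWHM definition is deliberately scale-free: intravital intensity
calibration is unknown and varies with depth, but the half-maximum width
of a bright tube over background does not depend on a global gain. Volume
uses the frusta sum `Σ π((rᵢ+rᵢ₊₁)/2)² Δsᵢ`; the single-cylinder figure
`π (mean_diameter/2)² · length` is reported alongside because descriptions
of this workflow commonly phrase volume that way.

## Front arrival and the flow estimator

Per arc position (every 2 µm) intensity is averaged over a disc of the
local radius, per frame; the mean of the first 5 pre-bolus frames is
subtracted. The arrival at a position is the first crossing of 50% of
that position's plateau (median of the last 10 frames), linearly
interpolated between the bracketing frames. Positions whose plateau does
not exceed 3× the baseline SD are flagged missing; multiple crossings use
the earliest and set a flag.

Sub-frame interpolation is not a refinement but a necessity: at 6 fps a
PT front at 4 nl/min through a 20 µm lumen moves ≈ 200 µm/s and crosses a
45 µm tubule in 1–2 frames.

Two estimators are reported:

- **Volumetric regression (primary):** least squares of `V(s)` on
  `t_arr(s)`; uses every position, robust to single-frame noise.
- **Two-point:** endpoint volume over endpoint transit time — the literal
  "volume change over time" — kept as a comparator; discrepancies surface
  in the quality flags.

Errors in the arrival times sit on the regressor axis, so the regression
slope carries a small attenuation bias that grows with flow (the transit
spans fewer frames); at 9 nl/min over a 200 µm tubule the bias is ~1%,
far below the noise floor of the application.

## Vessel diameter by maximal inscribed sphere

Per-slice equivalent circles overestimate the diameter of any vessel
oblique to the imaging plane — the usual geometry for afferent/efferent
arterioles. Instead:

1. Contours (or a mask) are voxelized; the mask must be one connected
   component.
2. The Euclidean distance transform (EDT) is computed with *physical*
   spacings (1 µm z-steps vs sub-micron pixels), via separable
   lower-envelope passes.
3. The centerline is the penalized-distance geodesic between the two
   geodesically farthest voxels: Dijkstra with edge cost
   `step_length / (EDT² + ε)`, which hugs the medial axis and naturally
   trims side branches to the longest path. The path is smoothed,
   resampled at 1 µm, and refined to the EDT ridge at sub-voxel
   resolution.
4. Local diameter = 2× the EDT at the centerline point. Numerically, the
   EDT at a sub-voxel point `x` is estimated as
   `min_v (EDT(v) + |c(v) − x|)` over nearby voxel centres — a tight bound
   by the 1-Lipschitz property that is exact inside cylinders — maximized
   over a small grid of perpendicular sub-voxel offsets so the result does
   not depend on where the true axis falls relative to the voxel lattice.
   No half-voxel surface correction is applied: the discrete EDT measures
   to background voxel *centres*, and over the continuum of boundary
   directions the minimal overshoot beyond the true surface is ≈ 0.
5. The first and last stretch of the path (one vessel radius each) are
   trimmed: geodesic endpoints sit on the mask surface and end caps
   shrink the inscribed sphere.

On cylinder phantoms (8–14 µm diameter, axis-aligned, 45°-tilted, and
curved) this recovers the mean diameter within one in-plane voxel.

## The synthetic world

No raw microscopy data are publicly deposited for this kind of study, so
validation rests on a generator whose ground truth is analytic. Its
defaults are one fixed, realistic stated world — they are documented here
and are not tuned against test outcomes:

| parameter | default | rationale |
|---|---|---|
| tubule length | 200 µm | typical visible superficial PT segment; chosen ex ante so the front spans ≥ 2 frame intervals at the top of the observed 0.5–9 nl/min range (a design requirement for sub-frame interpolation), and well above the 45 µm inclusion minimum |
| tubule radius | 10 µm | ~20 µm luminal diameter, typical mouse PT |
| glomerulus radius | 35 µm | superficial mouse glomerulus ~70 µm across |
| pixel size | 1 µm/px | speed-optimized time-series sampling |
| frame rate | 6 frames/s | the acquisition standard for this measurement |
| frames | 80 (13.3 s) | covers a 0.5 nl/min transit plus baseline and plateau windows |
| bolus arrival | 1.0 s | leaves 5 clean baseline frames |
| rise width | 0.15 s (10–90%) | dispersed bolus front; a step would make sub-frame interpolation untestable |
| background / peak | 20 / 150 photons | photon-budget realistic two-photon SNR ≈ 11 |
| noise | Poisson(signal·gain)/gain + N(0, 3) | standard photon-counting detector model |

Frames are rendered as an **integrating detector**: the stored value is
the mean of the logistic ramp over a one-frame-interval exposure centred
on the frame timestamp (closed form via the softplus antiderivative).
Instantaneous point-sampling is not how a scanned acquisition works, and
it matters: integration roughly halves the interpolation error of the
50%-crossing estimator at high flows.

The vessel phantom voxelizes a tube (constant or per-point diameter) along
any 3D centerline, plus an optional sphere standing in for the tuft, by
voxel-centre inclusion. A tube clipped by the stack faces is the normal
case (vessels cross the imaged volume); only a centerline leaving the
volume is an error.

**What the generator does not emulate** — hence what a green test does not
establish: optical PSF blur and depth-dependent scattering, breathing
motion, plasma pharmacokinetics of the tracer (peak intensity and rise
width are free parameters instead), separate vascular/nuclear spectral
channels, heterogeneous background structures, and photobleaching.
Recovery results on phantoms bound the algorithmic error, not the total
experimental error.

The demo cohort generator applies the group effects reported for this
design — snGFR reductions of ~0% (placebo), 44% (enalapril), 61%
(empagliflozin), 65% (combination) from group means of 4.2/4.24/4.12/6.03
nl/min with the printed between-nephron SDs — with a small log-normal
within-nephron perturbation (SD 8%), and caps nephrons per animal at
three (a warning, not an error, in the batch runner).

## Statistical choices

- The *nephron* is the paired unit, matching the per-nephron before/after
  design. Because nephrons within an animal are not independent, an
  animal-level sensitivity analysis (units averaged within animal first)
  is always reported alongside; the headline computation is unchanged.
- Classical Student t (Welch off) — the test named by the reporting
  convention this package follows; a toggle is out of scope.
- Šídák-adjusted pairwise comparisons use the pooled ANOVA MSE with
  `N − k` degrees of freedom (standard post-hoc practice; the error term
  is otherwise unspecified in the field's reporting).
- ANOVA is computed on group values as given; whether before/after deltas
  or raw values enter such comparisons is ambiguous in typical reports,
  and the caller decides what to pass.
- "~N%" figures are matched by truncation toward zero (44.34 → 44,
  61.17 → 61, 65.67 → 65) — the only rounding rule consistent with all
  three published values this package reproduces.
- Degenerate paired inputs follow documented conventions: identical pairs
  give `t = 0, p = 1`; zero-variance nonzero differences are reported as
  `p < .Machine$double.xmin` with a `zero_variance` flag.

## Numerical conventions and edge cases

- Arrival integrals use the trapezoidal rule on a 0.25 µm grid (verified
  against a 0.01 µm oracle to < 0.1%).
- The separable EDT uses a finite sentinel (10¹²) rather than `Inf` so the
  lower-envelope arithmetic stays exact; it is tested against a
  brute-force oracle on anisotropic random masks.
- FWHM not bracketed (profile never falls to half-max) flags the radius
  unreliable at that point; if no point is reliable, tracing fails with an
  instructive error.
- A tracer already present at t = 0 (no pre-bolus baseline) is an error
  instructing re-acquisition — the front criterion is undefined without a
  baseline.
- Front exiting the acquisition before the last frame sets a `truncated`
  flag in the ground truth rather than erroring, mirroring real truncated
  acquisitions.
- Self-intersecting refined paths error with the offending arc positions;
  disconnected vessel masks error with component sizes.
- Seeds for every stochastic step derive from a single integer; reruns are
  byte-identical (tested on the cohort CSVs).

## Known limitations

- 2D tracing on a single focal plane is the default; a volumetric time
  series would need 3D tracing, which this version does not implement.
- The inscribed-sphere diameter is a declared definition, validated on
  phantoms; parity with proprietary 3D reconstruction software is not
  attempted, as those definitions are unpublished.
- The regression estimator assumes a single advancing front; oscillatory
  or retrograde flow is rejected, not modelled.
- Phantom realism bounds what validation can show (see above); absolute
  accuracy on real tissue additionally depends on segmentation quality
  and optical effects outside this package's scope.
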