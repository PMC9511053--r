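# nephroflow

Quantification of **single-nephron glomerular filtration rate (snGFR)** and
**glomerular morphometry** from intravital two-photon microscopy of the
kidney, with a synthetic image generator providing analytic ground truth
for validation.

## Who this is for

Renal physiologists running longitudinal intravital multiphoton
experiments: a freely filtered fluorescent tracer (e.g. Lucifer Yellow) is
bolus-injected, a single-plane time series (6 frames/s) captures the dye
front filling the proximal tubule (PT) downstream of a superficial
glomerulus, and z-stacks (1 µm steps over ~120 µm) capture the afferent
and efferent arterioles and the capillary tuft. This package replaces the
ad-hoc FIJI/Imaris measurement steps with a scripted, tested, deterministic
pipeline.

## The core computations

**snGFR from tracer-front transit.** With flow `Q` (µm³/s) and luminal
cross-section `A(s) = π r(s)²`, the front arrives at arc length `s` at

    t_arr(s) = t0 + (1/Q) ∫₀ˢ A(u) du

so the cumulative luminal volume `V(s)` is linear in arrival time with
slope `Q`, and `snGFR = Q · 60/10⁶` nl/min. The tubule is traced
semi-automatically from user seed clicks (click order = flow direction),
radii come from the FWHM of perpendicular intensity profiles, arrivals
from 50%-of-plateau crossings with sub-frame linear interpolation, and
`Q` from least squares of `V(s)` on `t_arr(s)` (a two-point
"volume change over time" estimator is reported alongside).

**Vessel diameter by maximal inscribed sphere.** The vessel mask's
anisotropy-aware Euclidean distance transform yields a penalized-distance
geodesic centerline; local diameter = 2 × EDT at the centerline, an
orientation-robust definition (per-slice circles overestimate oblique
vessels). Glomerular volume = tuft voxel count × voxel volume.

**Paired statistics.** Per-nephron before/after paired Student t-tests,
one-way ANOVA with Šídák correction (`p_adj = 1 − (1 − p)^m`), percent
change of group means with tilde-integer reporting, and an animal-level
sensitivity analysis.

## Worked example

Simulate a nephron filling at the control-group mean snGFR, trace it, and
measure:

```r
library(nephroflow)

ph    <- nephron_phantom(true_sngfr = 4.24, seed = 42)   # nl/min
gen   <- generate_filling_series(ph)
gen$series
#> <image_series> 115 x 324 px (1 um/px), 80 frames @ 0.1667 s

seeds <- phantom_seeds(gen$truth, ph, n_seeds = 8, jitter_um = 0.5, seed = 1)
path  <- trace_tubule(gen$series, seeds)
path
#> <tubule_path> 202 points, length 200.7 um, mean diameter 19.92 um, volume 62599 um^3

measure_sngfr(gen$series, path)
#> <sngfr_result> snGFR = 4.216 nl/min (two-point 4.274), R^2 = 0.9992, 100% positions valid
```

The regression estimate (4.216 nl/min) recovers the simulated truth
(4.24 nl/min) within 0.6% under realistic photon noise; `R²` near 1 says
the volume–time relation is as linear as a single steady flow predicts.

Vessel morphometry on a 12.35 µm cylinder phantom (noisy, 0.5 µm pixels,
1 µm z-steps):

```r
ves <- generate_vessel_stack(vessel_phantom(diameter = 12.35,
         voxel_size = c(0.5, 0.5, 1), depth = 60, seed = 7))
reconstruct_vessel(ves$stack, mask = ves$truth$mask)
#> <vessel_measurement> mean diameter 12.61 um over 58 points (57.0 um)
```

Published group means reproduce the reported treatment effects
(these means ship as data in `inst/extdata/printed_group_stats.csv`):

```r
pc <- percent_change(4.24, 2.36)   # enalapril: control vs treated, nl/min
#> enalapril snGFR reduction: 44.34% (~44%)
```

A full demo cohort — 4 treatment groups × 5 nephrons, before/after —
runs end to end with `simulate_cohort()` + `run_pipeline()`, writing
per-unit JSON, a paired cohort CSV, group statistics, a Markdown report
and a decision log; reruns with the same seed are byte-identical.

## Command line

```
inst/cli/nephroflow simulate nephron --sngfr 4.2 --radius 10 --length 200 --seed 1 --out s.tif
inst/cli/nephroflow simulate vessel  --diameter 12 --depth 120 --zstep 1 --seed 1 --out g.tif
inst/cli/nephroflow sngfr   --series s.tif --sidecar s.yaml --roi s_roi.json --out res.json
inst/cli/nephroflow vessel  --stack g.tif --role afferent --out meas.json
inst/cli/nephroflow stats   --manifest cohort.csv --measure sngfr_nl_min --out report/
inst/cli/nephroflow pipeline --manifest manifest.csv --out report/
```

## Layout

- `R/` — synthetic data (`synthdata`), tubule tracing (`tubule`), snGFR
  estimation (`sngfr`), 3D vessel/tuft morphometry (`morphometry`),
  statistics (`stats`), formats + pipeline + CLI (`tiffio`, `pipeline`,
  `cli`)
- `src/` — Rcpp: anisotropic EDT, connected components, Dijkstra
- `vignettes/nephroflow-methods.Rmd` — models, assumptions, parameter
  rationale, numerical choices, limitations
- `tests/testthat/` — unit + property tests and `test-acceptance.R`
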