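# wavekymo

Quantification of segmentation-clock wave onset in gastrulating mouse
embryos from 3D+t light-sheet reporter recordings.

At gastrulation the presomitic mesoderm is a thin sheet curved around the
egg cylinder. A dynamic Notch-target reporter (LuVeLu) first shows a
quasi-synchronous tissue-wide **pulse**, then periodic **waves** that
appear to run from a proximal origin to the distal ends of the mesoderm.
`wavekymo` turns such recordings into the statistics that characterize
this onset, for imaging labs and modelers working on the segmentation
clock:

* **surface kymographs**: intensity sampled at equal arc-length steps
  along a spline line of interest (origin → intermediate surface point →
  distal end) on the curved tissue, after background reduction, recursive
  registration and center-of-mass axis alignment;
* **phase/period fields**: every kymograph row is sinc-detrended (cut-off
  220 min) and convolved with 600 complex Morlet wavelets (periods
  100–220 min); tracing the spectral power maxima ("ridges") yields
  instantaneous period and phase, re-stacked into phase kymographs;
* **wave statistics**: the wave number
  `q(t) = |φ_distal − φ_midline| / 2π` (q = 1: one full wave spans the
  mesoderm), the mesoderm length `L(t)`, the phase-gradient slope
  `q/L`, and proximal/distal period medians with IQRs sampled 2–6 h after
  wave onset. For a tissue with a linear period gradient these follow the
  phase-wave law `q(t) = t (1/P_prox − 1/P_dist)` with `q(0) = 0`;
* **cell-track flow**: selection of tracks staying within 30 µm of the
  line of interest for ≥ 300 consecutive minutes, vector-field averaging
  of their velocities and streamline export.

A synthetic phantom embryo (hemisphere-capped cylinder shell with a
proximo-distal period gradient, pulse, noise, growth and advected tracks)
carries analytic ground truth for every stage; all headline numbers in the
tests are parameter-recovery checks against it.

## Worked example

The whole chain runs self-contained on the default phantom (periods
133 min proximal / 153 min distal, growing arc, additive noise, 100 frames
at 10-min intervals):

```r
library(wavekymo)
bundle <- run_pipeline(list(seed = 1, flow = TRUE))

bundle$period_gradient
#> <period_gradient>
#>    region   median      iqr  n
#>  proximal 132.0534 1.051753 24
#>    distal 149.9833 1.502504 24
#>   gradient (distal - proximal medians): 17.93 min

bundle$flow
#> <vector_field> 36 occupied cells, 1100 samples, mean speed 0.201 um/min
```

The proximal median recovers the generator's 133 min within a minute; the
distal series is read 20 px (≈ 41.8 µm) inside the domain boundary, where
the phantom's true period is ≈ 150.2 min, and recovers that value — the
distal-minus-proximal gradient of ≈ 18 min reflects the 20-min generator
gradient sampled at those locations. The flow field recovers the 0.1–0.3
µm/min advection speeds (mean 0.2). `bundle$stats` holds `q(t)`, `L(t)`
and `slope(t)` per timepoint; on this phantom `q` grows linearly from 0
and the slope increases monotonically, as the phase-wave model predicts.

The same chain runs from a rendered 3D volume instead of the direct
kymograph render with `run_pipeline(list(mode = "volume", ...))`, which
exercises background reduction, registration, alignment, ray-cast landmark
localization and spherical surface sampling on the way to the identical
statistics.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run-pipeline.R --config my-config.yaml --out results/
```

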