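---
title: "Quantifying the onset of segmentation-clock waves from surface kymographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the onset of segmentation-clock waves from surface kymographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavekymo)
```

## The problem

During mouse gastrulation the segmentation clock — the oscillatory
gene-expression system that times somite formation — switches on in the
nascent mesoderm. A dynamic Notch-target reporter (LuVeLu) read out by
light-sheet imaging shows a characteristic sequence: a quasi-synchronous,
tissue-wide *pulse* of reporter activity, followed a few hours later by
periodic *waves* that appear to travel from a proximal origin towards the
distal ends of the presomitic mesoderm. Because the mesoderm at this stage
is a thin sheet curved around the cup-shaped epiblast ("egg cylinder"),
meaningful quantification must follow the curved tissue surface rather than
a fixed projection plane.

`wavekymo` implements the full quantification chain: volume conditioning,
surface-kymograph extraction along a three-anchor line of interest (LOI),
wavelet-based phase and period extraction, and the derived wave statistics
— wave number $q$, mesoderm length $L$, phase-gradient slope $q/L$, and
proximal/distal period sampling — plus cell-track flow analysis. A phantom
embryo generator with analytic ground truth exercises every stage.

## The model behind the statistics

The working model is a *phase wave*: each tissue element at arc distance
$s$ from the wave origin oscillates autonomously with local period $P(s)$,

$$\varphi(s, t) = \frac{2\pi\,t}{P(s)},
  \qquad P(s) = P_\mathrm{prox} + (P_\mathrm{dist} - P_\mathrm{prox})
  \frac{s}{L},$$

so no signal propagates — the apparent wave is the spatial gradient of
phase built up by the period gradient. Two consequences drive the
statistics:

* the **wave number** $q(t) = |\varphi(L, t) - \varphi(0, t)| / 2\pi$
  grows linearly, $q(t) = t\,(1/P_\mathrm{prox} - 1/P_\mathrm{dist})$,
  starting from synchrony ($q(0) = 0$; $q = 1$ means one full wave spans
  the tissue);
* the **phase-gradient slope** $q/L$ is the local phase difference per
  micrometer, the natural intensive measure when the tissue grows.

The package measures all three quantities from data and, for phantoms,
compares them against these closed forms.

## Pipeline stages and their tunables

### Volume conditioning

Raw volumes are corrected by *temporal background reduction*: the mean of a
fixed voxel box outside the specimen is subtracted per frame and a constant
offset (default 1000 counts) added back, pinning the background level
against slow drifts; values are floored at zero, since intensities are
unsigned. Frames are then registered *recursively*: frame $n{+}1$ is
registered against the already-transformed frame $n$, and the procedure
propagates in both directions when the reference is not the first frame.
The pairwise estimator is pluggable; the built-in default estimates
integer-voxel translations from the cross-correlation peak, which is exact
on rigid integer drifts. Axis alignment thresholds every frame (default
1030 counts), sums the binary masks over time, and translates the dataset
so the summed-mask center of mass (COM) sits at the image center, followed
by an operator-supplied rotation. Finally the z-axis is resampled to
isotropic resolution (factor `"auto"` derives, e.g., 3.59 from 7.5 um
z-steps over 2.088 um pixels).

### The line of interest and surface kymographs

Three anchors define the LOI per frame: the wave origin, a distal end
(left or right), and an intermediate surface point found by casting a ray
from the COM through the origin–distal midpoint and taking the intensity
argmax (ties resolve towards the COM; a cubic smoothing spline over time
irons out per-frame jitter of the argmax).

The path through the anchors is the **circular arc** (the unique
constant-curvature conic) through the three points, degenerating to a
straight polyline for collinear anchors. A quadratic (parabolic)
interpolant was considered first, but its arc length on a quarter-circle
anchor triple is 0.53% short — outside the 0.5% accuracy this package
promises for curved-geometry lengths — whereas the circular arc is exact on
circular meridians and closer on any nearly-circular surface arc. The arc
is chorded into 100,000 equal-parameter segments; cumulative chord lengths
are tabulated so integer-distance lookups are a table search, and one
kymograph row corresponds to one pixel step (2.088 um) of arc distance.
Intensities are collected as means over a 12-pixel-diameter sphere
(about 25 um) after 3D Gaussian smoothing (sigma 6 px, about 12.5 um);
spheres at the volume border average their in-bounds voxels, since distal
anchors may touch the border. The kymograph fixes the origin series at the
midline, left arc above, right arc below; cells beyond the current arc
length carry the fill value 1067 and are masked invalid.

### Phase extraction

Frames before the (manually determined) wave onset are cropped. After a
spatial Gaussian (sigma 5 px ~ 10.4 um), every row is detrended by
subtracting a Blackman-windowed sinc low-pass at cut-off period 220 min.
The kernel half-width is twice the cut-off period: at half-width 1.5x the
filter's transition band still attenuates a 150-min oscillation by ~6%,
while 2x brings the analysis band ripple below 4% interior (0.3% deep
interior) at the cost of a modestly longer minimum series.

Detrended rows are convolved with 600 complex Morlet wavelets scanning
periods 100–220 min. The central angular frequency is $\omega_0 = 2\pi$,
so wavelet scale equals Fourier period and the power maximum of a sinusoid
falls on its own grid period; coefficients are normalized so a
unit-amplitude sinusoid has ridge power 1 away from the edges, and phase 0
coincides with an oscillation maximum (cosine convention). The *ridge* is
the per-column power argmax (ties towards the smaller period, no continuity
penalty); its argument gives the instantaneous phase, wrapped to
$(-\pi, \pi]$. Re-stacking per-row ridge phases yields the phase kymograph.
The edge-effect margin (two periods from either end for this wavelet,
whose Gaussian envelope has standard deviation one period) is reported
but not masked; tests assert accuracy only outside it.

### Wave statistics

Only one side of the kymograph (default left/top) enters the statistics.
Per time column, phases are unwrapped spatially from the midline outward
over the contiguous valid run, 20 px (~41.8 um) at the distal end are
cropped off, and $q$ is the absolute midline-to-end difference over
$2\pi$; the cropped column length times the spatial pixel is the mesoderm
length $L$, and slope $= q/L$ (so slope times $L$ reconstructs $q$ exactly
by construction). The unwrap direction is fixed for reproducibility, but
$q$ is gauge-invariant under constant phase offsets either way.

Period sampling mirrors the same geometry on the intensity kymograph: the
proximal series follows the midline, the distal series follows the domain
boundary contour shifted 20 px towards the midline (staying inside the
oscillatory domain while moving with tissue expansion); both are corridor
means 8 px (~16.7 um) wide, pushed through the same detrend–wavelet–ridge
chain. Ridge periods collected 2–6 h after onset (24 samples per region at
10-min frames; the count scales with the frame interval) reduce to median
and IQR.

Note one deliberate convention: the distal readout sits ~41.8 um inside
the domain edge, so its ground truth on a phantom is $P$ *at the sampled
contour*, not $P_\mathrm{dist}$. On a 200-um phantom arc that distinction
is 3–5 min; on real mesoderm (400+ um) it shrinks proportionally. Tests
compare against the contour value and, where the arc is long enough, also
against $P_\mathrm{dist}$.

### Cell-track flow

Track clocks are aligned so $t = 0$ falls 260 min after the pulse peak.
Tracks are kept when they remain within 30 um of the frame-matched LOI for
at least 300 consecutive minutes ("over 300 min" is read as $\ge$ 300; the
boundary case is tested). Distance to the path is the minimum over chord
samples — exact point-to-curve minimization is pointless at this sampling
density. Finite-difference velocities (central interior, one-sided ends)
are binned on a (arc distance, signed lateral offset) grid; the lateral
sign is taken along the anchor-plane normal. Sample counts are conserved by
construction, and streamlines are a visualization aid, not a statistic.

## The phantom generator

The phantom idealizes the embryo as a hemispherical cap (the distal tip)
on a cylinder, with the oscillation phase field axisymmetric in arc
distance from the cap apex. The wave origin therefore sits at the apex and
the two distal ends on the cylinder rim — geometrically mirrored relative
to the real embryo (origin proximal), but preserving exactly what the
analysis consumes: a single origin, two arcs over a curved surface, and a
linear period gradient in relative arc position. Shell intensity is
`background + pulse(t) + A (1 + cos phi(s, t)) / 2` with a spatially
uniform Gaussian-in-time pulse (reflecting the quasi-synchronous rise),
additive Gaussian noise clipped at zero, and linear arc growth. Defaults
are the measured study conditions: periods 133/153 min, 10-min frames,
growth and advection in the 0.1–0.3 um/min motility range. No published
amplitude or signal-to-noise calibration exists for this reporter, so the
intensity amplitudes (background 1100, oscillation 200, pulse 400, noise
sd 20 counts) are chosen once as plausible for this reporter class and
not tuned.

What the phantom does **not** emulate: a point-spread function,
scattering, bleaching, nuclear texture, irregular embryo geometry, or
period gradients that change shape over time. Passing recovery tests
therefore demonstrate correctness of the quantification chain, not
robustness to every property of real microscopy data.

Each generator (volume, kymograph, tracks) draws from its own seeded
stream derived from `rng_seed`, so stages can be regenerated independently
and bit-identically.

## Numerical choices and degenerate inputs

* Volume translation uses integer voxel shifts (fill = background offset
  1000 so later thresholding is unaffected); rotation resamples
  trilinearly about the COM.
* Landmarks are carried through registration and alignment translations;
  when a nonzero rotation is used, annotations are expected in the aligned
  frame.
* Constant ray profiles, all-equal intensity profiles, empty masks, empty
  track selections, sub-Nyquist wavelet grids, windows exceeding the
  recording and arcs outgrowing their kymograph all have defined behavior
  (documented errors, warnings, or flagged `NA`s) rather than silent
  misbehavior.
* The wavelet grid spacing is 120/599 ~ 0.2 min; ridge-period quantization
  is therefore negligible against the stated tolerances.

## Problem sizes used in the test-suite

The shipped tests run the full 3D chain on a 128x128x128-voxel phantom at
2.088 um spacing over 60 frames (about 10 h of recording), the size at
which the whole analysis — rendering, registration, alignment, surface
sampling, wavelets, statistics, flow — completes in a few minutes on one
core; byte-level determinism of the pipeline outputs is demonstrated on a
reduced phantom so the double run stays cheap. Direct-render kymograph
phantoms (the fast path that bypasses 3D rendering) carry the
parameter-recovery burden at full temporal length.

## Known limitations

* The pairwise registration estimator is translation-only; rotational
  drift would need a user-supplied estimator (the recursive composition
  accepts any).
* The circular-arc LOI deviates from the true meridian where a cap joins a
  straight flank (worst near the junction); the induced kymograph
  distortion is a few micrometers and is covered by the recovery
  tolerances.
* Phase extraction trusts the single power-maximum ridge; signals with two
  comparably strong spectral components will ridge-hop (the
  larger-amplitude component wins, which the tests assert).
* With 10-min frames the 2–6 h window yields 24 period samples per region;
  other frame intervals change that count proportionally.
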