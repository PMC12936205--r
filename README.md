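# synaptrack

Quantitative analysis of T-cell receptor (TCR) microcluster transport and
cortical actin dynamics at the immunological synapse, for two-channel
time-lapse fluorescence movies (a TCR channel plus an actin/LifeAct
channel), together with a synthetic movie generator that provides full
ground truth for validation.

When a T cell engages antigen it forms a radially organized synapse with
an actin-depleted centre (cSMAC). TCR microclusters are transported across
this interface: classically inward with the retrograde actin flow, but in
primary T cells a large fraction also moves outward, carried by expanding
actin wavefronts. `synaptrack` implements the measurement chain needed to
quantify this:

- **Detection** — 8-bit conversion, Gaussian filtering (radius 3 px),
  percentile thresholding, intensity-weighted sub-pixel centroids, and an
  actin-derived positive mask restricting analysis to the dSMAC/pSMAC
  annulus.
- **Predictive tracking** — features are linked by minimizing the distance
  to the position predicted from each track's instantaneous velocity,
  `P(t1) = x(t0) + v(t0)(t1 - t0)` with
  `v(t0) = (x(t0) - x(t-1)) / (t0 - t-1)`; tracks with end-to-end
  displacement below 3.5 px (146 nm) are discarded as non-motile, and a
  motile track is *anterograde* when its final radial distance from the
  synapse centre exceeds its initial one (*retrograde* otherwise).
- **Actin flow by PIV** — windowed FFT cross-correlation (32 px windows,
  16 px overlap) with overlap-envelope normalization, temporal background
  subtraction and sub-pixel Gaussian peak interpolation, summarized as an
  anterograde vector fraction and mean speed, with a particle-based
  tracking route as cross-validation.
- **Actin wavefronts** — 5x5 Gaussian smoothing followed by Sobel
  gradient-magnitude band-pass edge detection (10-40 AU), and a
  TCR-wavefront colocalization score (an edge pixel within the eight
  nearest pixel neighbours, ~60 nm, of a TCR position).
- **Tracer model** — 100 tracers with default 50 nm/s retrograde motion
  that couple either to wavefronts within a 300 nm scan radius (mode 1)
  or to the local PIV flow above a speed threshold (mode 2), compared to
  reference trajectories through KDE-smoothed outward/inward run-time
  distributions and their mean squared error.
- **Synthetic data** — `make_profile()` / `simulate_ground_truth()` /
  `render_movie()` generate ground-truth scenarios (drifting and
  diffusive clusters, expanding wavefront arcs, cluster-wave coupling,
  analytic flow fields) and render them into noisy 16-bit two-channel
  movies with 41.6 nm pixels. Built-in profiles encode four experimental
  conditions: `primary`, `jurkat`, `wasp_ko`, `ck666`.

## Worked example

```r
library(synaptrack)

profile <- make_profile("primary", list(seed = 1))
gt      <- simulate_ground_truth(profile)
movie   <- render_movie(gt, profile)          # list(tcr =, actin =) ImageStacks
res     <- analyze_movie(movie$tcr, movie$actin)

print(res$geometry)
res$tcr$anterograde_fraction
res$flow$anterograde_fraction
res$colocalization
detection_accuracy(detect_features(movie$tcr), gt)
```

Output:

```
CellGeometry: centre (81.5, 81.5) px, R = 71.9 px, cSMAC = 17.0 px
motile TCR tracks: 167
anterograde fraction: 0.467
mean TCR speed: 44.5 nm/s
PIV anterograde flow fraction: 0.438
TCR-wavefront colocalization: 0.712
detection accuracy vs ground truth: 1.000
```

The recovered geometry matches the simulated 3 µm cell (72.1 px) and
0.75 µm cSMAC. For this primary-cell scenario roughly 45% of motile TCR
tracks end farther from the centre than they started (wave-coupled
transport), mean step speed is ~44 nm/s, ~44% of above-noise PIV vectors
point outward, and ~71% of track points sit within ~60 nm of a detected
actin wavefront edge. Per-cell values fluctuate by a few percentage
points between seeds; multi-cell means are the stable quantities.

`run_pipeline()` (or the thin CLI in `inst/scripts/synaptrack-pipeline.R`)
orchestrates multi-cell, multi-condition runs from a YAML configuration,
aggregates per-cell metrics as mean ± SEM and compares groups with the
Mann-Whitney test. `run_simulation()` exposes the tracer model directly.

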