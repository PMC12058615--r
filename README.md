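# afmlattice

Quantitative analysis of surface-assisted DNA origami lattice assembly
from time-resolved (high-speed) AFM height-image stacks.

Triangular DNA origami monomers adsorb from solution onto mica and, being
laterally mobile, pack into a 2D hexagonal lattice. Filming this with
HS-AFM yields a stack of calibrated height frames; the scientific readout
is (i) the surface coverage Θ(t) and the time to monolayer formation,
(ii) the lattice order per frame, and (iii) the long-range order of large
overview frames. This package implements the full pipeline for users who
have such stacks (or want to validate the pipeline on synthetic ones):

* **I/O** — calibrated frame series (CSV height grids or multi-page TIFF
  + JSON sidecar), with a fixed physical coordinate convention.
* **Preprocessing** — plane leveling and robust per-scan-line flattening.
* **Detection** — thresholding (automatic or fixed, per-time-range
  schedules), 8-connected segmentation with hole filling, monolayer
  splitting by watershed, monomer/dimer/cluster classification, and
  coverage as the above-threshold area fraction.
* **Lattice order** — the Delaunay-angle order parameter n(Θ₆₀): the
  number of Delaunay interior angles within 60° ± 5° per µm² of image.
  A perfect triangular lattice of density ρ gives n(Θ₆₀) → 6ρ; disorder
  drains the count.
* **Kinetics** — pseudo-first-order fits Θ(t) = Θ∞(1 − e^(−k(t−t₀))),
  time-to-monolayer, extra-sum-of-squares F-tests between curves, and
  one-way ANOVA on final order values.
* **Long-range order** — windowed 2D FFT with a hexagonal correlation-peak
  score (six first-order peaks at radius 2/(√3·a) cycles/nm).
* **Synthetic ground truth** — lattice/CSR/packed scene generators, an
  AFM-like renderer, and a random-sequential-adsorption simulator with
  injection lag, transport-capped arrivals, desorption and relaxation.

The numbered scripts under `analysis/` run the whole study on simulated
data: `01_simulate_series.R` (concentration series end to end),
`02_coverage_kinetics.R`, `03_lattice_order.R`, `04_fft_longrange.R`,
`05_report.R`. Their tables land under `results/`.

## Worked example

```r
library(afmlattice)

# a perfect hexagonal lattice, 110 nm spacing, 1 um^2 field
scene <- make_lattice_scene(a = 110, field_um = 1, jitter_sigma = 0, seed = 1)
tri   <- triangulate_angles(scene$positions, frame_area_um2 = 1)
order_parameter(tri)
#> order_result: n(Theta60) = 510.0 per um^2 (510 of 540 angles in 60 +/- 5 deg, area 1 um^2)

# render it as an AFM frame and detect the particles back
frame <- render_frame(scene, pixel_size = 5, noise_sigma = 0.3, blur_nm = 3,
                      seed = 2)
flat  <- flatten_lines(level_plane(frame), order = 1)
field <- detect_particles(flat, detection_params(min_area_nm2 = 3000,
                                                 ref_area_nm2 = 6235))
field
#> particle_field: 101 particles, coverage 0.938, t = 0.0 s

# coverage kinetics on a synthetic adsorption curve
curve <- synth_coverage_curve(theta_inf = 0.9, k = 0.01, noise_sigma = 0.02,
                              n_points = 600, seed = 3)
fit <- fit_pseudo_first_order(curve)
fit
#> pfo_fit: theta_inf = 0.8998 (se 0.0013), k = 0.010047 s^-1 (se 6.2e-05), rss = 0.243, n = 600
time_to_monolayer(curve, fit)$t_ml_analytic
#> [1] 298.1628
```

The lattice has 105 sites in the field, each interior site contributing
six 60° angles (510 counted; the shortfall from 6ρ = 630 µm⁻² is the
convex-hull boundary). On the rendered monolayer the triangles touch and
merge, so detection recovers 101 watershed-split particles of the 105
(coverage 0.94 of the frame is above threshold), and the kinetics fit
recovers Θ∞ = 0.9 and k = 0.01 s⁻¹ to a fraction of a percent from a
noisy trace; the analytic 95 %-saturation crossing −ln(0.05)/k lands at
≈ 300 s.

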