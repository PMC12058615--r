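---
title: "Quantifying DNA origami lattice assembly from high-speed AFM image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA origami lattice assembly from high-speed AFM image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmlattice)
```

## The system and the measurement problem

Triangular DNA origami nanostructures adsorb electrostatically onto mica
from solution and, because they remain laterally mobile on the surface,
maximize their packing by arranging into a two-dimensional hexagonally
close-packed lattice. High-speed AFM films this process as a stack of
height images: each frame is a grid of heights in nanometres with a known
pixel size and a timestamp relative to sample injection. Three questions
drive the analysis:

1. **How fast does the monolayer form?** Surface coverage
   $\Theta(t) \in [0, 1]$ rises to a saturation plateau; its trace is
   summarized by a pseudo-first-order fit.
2. **How ordered is the lattice, and how does order evolve?** Quantified
   per frame by a Delaunay-angle order parameter.
3. **How ordered is the lattice over micrometre length scales?** Assessed
   on large overview frames through the Fourier magnitude spectrum.

The package implements the full chain — calibrated I/O, flattening,
segmentation, order metrics, kinetics and statistics — plus a synthetic
scene generator and an adsorption simulator that provide exact ground
truth for every step.

## Preprocessing

Raw AFM frames carry a sample tilt and per-scan-line offsets.
`level_plane()` subtracts the least-squares plane. `flatten_lines()`
removes per-line offsets in two stages chosen to work at *any* surface
coverage: first a cumulative alignment on the median of adjacent-line
differences — adjacent scan lines image nearly the same topography, so the
differential median isolates the scan-line offset even on closed
monolayers, where any line-by-line background mask would pick inconsistent
reference levels (sometimes gaps, sometimes particle tops) and wreck the
height histogram. Because cumulative alignment performs a random walk
under pixel noise (about 1 nm of drift across 300 rows at 0.6 nm noise,
enough to clip particles near a frame edge), each line is then re-anchored
on the weighted mean of its background pixels, with *smooth global*
weights: a logistic taper centered at the frame's median + 1 MAD. The
global weights select the same height class on every line, and their
smoothness makes the iterated anchor-and-fit cycle contract to a fixed
point where a hard mask oscillates — so the operation is idempotent, which
the test suite asserts to $10^{-6}$ nm (measured ~$10^{-8}$). For
`order >= 1` the non-constant polynomial terms are fitted per line under
the same weights; intercepts are deliberately excluded from those fits
because line levels belong to the anchor (fitting both sets up a sustained
tug-of-war). Lines with essentially no background keep the differential
alignment only. Flattening never changes frame geometry or timestamps.

## Particle detection and surface coverage

`detect_particles()` thresholds the flattened height image. In automatic
mode the threshold maximizes the inter-class variance of the height
histogram (Otsu); since that construction always "finds" a split — on an
all-noise frame, or by splitting the noise itself when the foreground
fraction is tiny — the split is accepted only when it explains a clearly
bimodal histogram: the between-class variance fraction
$\eta = w_0 w_1 (\mu_1 - \mu_0)^2 / \sigma^2$ equals 0.637 when Otsu
splits pure Gaussian noise (a distributional constant), so the cut is
placed just above it, at 0.645. Below it, a robust noise-based cut
(sigma-clipped median + 3 MAD) is used instead — the right answer
precisely in the background-dominated regime where Otsu fails, with
spurious noise pixels removed downstream by the minimum-area filter. A fixed
threshold in nm is also available, and a `param_schedule()` can assign
different `detection_params()` to different time ranges, mirroring how
detection is calibrated per time range in practice (sparse early frames and
closed late monolayers need different settings).

Above-threshold pixels are grouped with 8-connectivity, interior holes up
to `max_hole_nm2` are filled (AFM triangles often image with a central
cavity that must not split a particle), components below `min_area_nm2`
are discarded, and centroids are intensity-weighted positions in physical
nm — x rightward, y upward from the bottom-left corner, pixel centers at
half-pixel offsets. **Coverage is the above-threshold pixel fraction after
filtering**, not particle count times a nominal footprint: the definition
survives the monolayer regime where components merge and counting fails.

Once the layer closes, lattice analysis still needs per-triangle positions.
Components larger than the cluster band are re-segmented by a watershed on
the distance transform of the raw (pre-hole-filling) mask — the pores
between touching triangles are exactly the boundaries the watershed needs.
The watershed tolerance scales with the expected particle radius
(0.1 × lattice constant in pixels). On rendered monolayers this recovers
per-particle seeds with high fidelity (asserted in the test suite against
generator truth).

Classification is by area band relative to a reference monomer area
(default: the field's median component area): below 1.5× is a monomer,
1.5–2.5× a dimer, above 2.5× a cluster. The dimer fraction
dimers/(monomers + dimers) summarizes blunt-end-stacked pairs, which
appear as single 8-connected components of twice the monomer area.

## The Delaunay-angle order parameter

`triangulate_angles()` computes the Delaunay triangulation of the detected
centroids (via the `deldir` package) and all interior angles;
`order_parameter()` counts angles in the half-open window
$[60° - w, 60° + w)$ with $w = 5°$ by default and divides by the analyzed
area, giving $n(\Theta_{60})$ in µm⁻². For a perfect triangular lattice
every interior lattice point carries six incident 60° angles, so
$n(\Theta_{60}) \to 6\rho$ (ρ = particle density) as the field grows, with
a deficit proportional to perimeter/area; disorder spreads the angle
distribution away from 60° and the count drops. Because the count is
dominated by the bulk, the parameter is less sensitive to image boundaries
than nearest-neighbor-distance statistics.

Numerical choices:

* **Half-open window.** "±5°" leaves the edge convention open; the
  half-open window counts each angle exactly once at the bin edges.
* **Hull handling.** Triangles with an edge on the convex hull are flagged
  but *included* by default, and normalization uses the full frame area;
  `include_hull = FALSE` reproduces the interior-only choice. The
  difference between the two shrinks as perimeter/area, which is tested.
* **Degenerate configurations.** A perfect lattice is maximally
  degenerate input for any Delaunay code (every quad of neighbors is
  cocircular, every row collinear). A deterministic tie-breaking jitter —
  $\max(10^{-6}\ \mathrm{nm},\ 10^{-7} \times \mathrm{span})$, keyed to the
  point index — is applied *only* for the triangulation, large enough to
  clear `deldir`'s internal tolerance on fields up to several µm; angles
  are computed from the unjittered coordinates, so exact lattices keep
  exact 60° angles (asserted to $10^{-6}$ degrees). Zero-area sliver
  triangles that `deldir` emits along exactly collinear runs are discarded
  (they are not simplices; the filter drops triangles whose largest angle
  exceeds $180° - 10^{-5}°$).
* **Angles** come from the arc-cosine of normalized edge-vector dot
  products clamped to $[-1, 1]$.

As a null reference, the fraction of Delaunay angles in $[55°, 65°)$ for
complete spatial randomness is checked against an independent Monte-Carlo
oracle (`scipy.spatial.Delaunay` on fresh uniform draws, ≥10⁵ triangles);
ordered lattices must exceed it.

## Coverage kinetics

`fit_pseudo_first_order()` fits
$\Theta(t) = \Theta_\infty\,(1 - e^{-k (t - t_0)})$ with $t_0$ fixed to the
first timestamp, by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`). Starting values come from the data — $\Theta_\infty$
from the last decile's mean, $k$ from a log-linearization of the rising
part — and the fit restarts from a fixed grid of rate scalings
(×1, ×¼, ×4, ×1/16, ×16), keeping the best converged residual sum of
squares; saturating noisy traces otherwise trap local minima. Bounds keep
$\Theta_\infty \in (0, 1.2]$ and $k > 0$. Noiseless model curves are
recovered exactly and the noisy-recovery error is bounded in the tests.

`time_to_monolayer()` defines $t_{ML}$ as the earliest observed timestamp
with $\Theta \ge f\,\Theta_\infty$, with $f = 0.95$ by default — the
saturation criterion is exposed as a flag because "densely packed
monolayer" is not otherwise quantified — and also reports the analytic
crossing $t_0 - \ln(1 - f)/k$. Series that never reach the target return a
flagged missing value.

`compare_datasets_ftest()` compares curves by the extra-sum-of-squares
F-test: a shared-parameter fit over the pooled series (each keeping its own
time origin) against independent per-series fits, omnibus and pairwise,
with Holm adjustment over pairs. `final_order_anova()` runs the one-way
ANOVA on final lattice order, with the helper `select_final_orders()`
picking five evenly spaced $n(\Theta_{60})$ values from the last 50 s of
each series; all-identical input returns F = 0, p = 1 by stated convention
rather than NaN.

## Long-range order from the Fourier spectrum

`compute_spectrum()` applies a raised-cosine (Hann) window — edge leakage
would otherwise mimic a diffuse background — and returns the zero-centered
2D magnitude spectrum with axes in cycles/nm. A triangular lattice with
constant $a$ concentrates power in six first-order peaks at radius
$2/(\sqrt{3} a)$, 60° apart.

`hexagonal_peak_score()` makes the qualitative sharp-peaks-versus-diffuse-
background comparison of image FFTs computable; it is labeled as a
quantitative extension in all outputs. Within a radial band it finds up to
six azimuthally separated (≥30°) local maxima of a 5×5 box-smoothed
magnitude — smoothing integrates a peak's main lobe whether or not it falls
on a DFT grid point, which is what makes the score stable under lattice
rotation. Per one-bin annulus, two backgrounds are estimated: the lower
quartile, robust to contamination by the peaks' own smoothed skirts,
decides *detection* (a maximum counts as a peak at ≥3× it; on white-noise
frames this detector stays silent, which is tested over seeds); the median
normalizes the reported peak-to-background *score*. Peak positions are
refined to sub-bin accuracy by the squared-magnitude centroid of the raw
spectrum around each maximum — at the first-order radius of a 1 µm frame
one grid cell spans about 5° of azimuth, far too coarse for peak angles
otherwise. The score decreases monotonically with positional disorder at
fixed density; rotation changes it by about 10 % on rendered lattices
(rotating the lattice against the raster genuinely redistributes spectral
leakage), so the rotation-invariance test uses a 15 % band rather than a
tighter one.

## What the synthetic data emulate — and what they do not

`make_lattice_scene()` builds triangular-lattice centroids (default
$a = 110$ nm) with independent Gaussian positional jitter, random
vacancies, and grains realized as Voronoi regions of random seeds, each
with its own lattice rotation. `make_poisson_scene()` is the CSR baseline.
`make_adsorbed_scene()` places entities with an exclusion distance and
plants a controlled fraction of dimers as vertex-to-vertex pairs (the
contact geometry of blunt-end stacking), slightly overlapped so the pair
always rasterizes as one connected component. `render_frame()` rasterizes
equilateral triangles (default side 120 nm, height 2 nm — typical for the
triangular origami monomer, and parameters rather than constants), then
applies Gaussian blur as a simple tip-broadening proxy, per-pixel height
noise, and per-line offsets. All generators are pure functions of
(parameters, seed).

`simulate_assembly()` is a random sequential adsorption model on a
continuous field: per frame, a Poisson number of adsorption attempts lands
uniformly; an attempt succeeds iff no adsorbed particle lies within the
exclusion radius; particles desorb independently with a per-frame
probability; and with a per-frame relaxation probability a particle snaps
to the nearest free site of a reference lattice — a deliberately minimal
proxy for surface mobility that anneals defects. Without relaxation the
simulation jams strictly below the close-packing coverage, as RSA must;
with relaxation, late-frame order exceeds matched relaxation-free runs
(both tested).

The arrival rate is
$\min(\text{rate} \times c_s(t),\ \text{max\_flux})$ with
$c_s(t) = c\,(1 - e^{-t/\tau_d})$: the exponential ramp is the simplest
monotone model of the near-surface concentration rising after injection,
with larger $\tau_d$ emulating injection of a small concentrated bolus far
from the surface. The ceiling `max_flux_per_um2` models the transport
bottleneck of the liquid cell — only so many particles can diffuse to the
surface per unit time regardless of nominal concentration. The cap is what
produces concentration-independent monolayer times at high concentration:
for any arrival model whose flux is strictly proportional to $c$, doubling
$c$ must shorten $t_{ML}$ by at least $1 - 1/\sqrt{2} \approx 29\%$ (the
ramp integral is convex, so the required dose is reached in its quadratic
regime at best), so a saturating mechanism is not an optional nicety but
the only way to obtain near-independence. With the cap binding, doubling
the concentration moves the averaged $t_{ML}$ by a few percent; with no
lag and no cap, $t_{ML}$ scales inversely with the arrival rate — both
regimes are exercised by the acceptance tests, using the observed
0.95-of-plateau crossing averaged over four replicate runs per arm
(a single crossing sits on the flat jamming tail and is noisy).

Features of real HS-AFM data deliberately *not* emulated: tip–sample
interaction physics (beyond isotropic blur), scanner drift and creep
between frames, streak artifacts, height calibration error, and the
electrostatics of the origami–mica interaction. Passing tests therefore
show that the analysis recovers known ground truth under the stated noise
model, not that it is robust to every instrumental artifact.

## File formats

The native on-disk format is a directory of per-frame CSV height grids
plus a JSON sidecar (`series_id`, `scan_size_um`, `resolution_px`,
`frame_rate_fps`, `start_offset_s`, `concentration_nM`, optional
`timestamps_s`). Heights are written at nine significant digits after
rounding to float32, which makes the read/write round trip bit-exact at
float32 precision; explicit per-frame timestamps override computed ones,
because frame rates change mid-experiment. Multi-page TIFF is supported on
the read side (values taken as nm, or rescaled through optional
`height_scale`/`height_offset` sidecar keys); CSV was chosen as the native
format because the common TIFF writers for R clamp float samples outside
[0, 1], which cannot represent flattened (signed) heights losslessly.

## Problem sizes

The test-suite and acceptance computations use 1–4 µm fields at 200 px per
µm-equivalent resolution, 100–1500 particles per frame, series of 10–50
frames, 50-replicate fitting studies and 20-seed disorder sweeps; the CSR
null uses ≥10⁵ triangles. These sizes give stable statistics for every
asserted property while keeping a full run of tests plus acceptance script
in the tens of minutes on one CPU. The pipeline streams frames one at a
time (memory stays flat in series length) and processes a 240-frame,
200×200 px series — simulation, rendering, flattening, detection, order
and kinetics — in a few minutes on one CPU.

## Known limitations

* The detector is a functional stand-in for the interactive calibration
  workflow used with real data; its absolute coverage at a given threshold
  differs from a human-calibrated one by up to a few percent of area on
  blurred edges.
* $n(\Theta_{60})$ saturates once per-particle positions stop being
  resolvable; at coverages where the watershed under-segments the
  monolayer, order is underestimated rather than flagged.
* The F-test assumes independent homoscedastic residuals; coverage traces
  from a single film are serially correlated, so its p-values are
  anticonservative on real data and best read comparatively.
* The simulator's relaxation rule (snap to the nearest free reference
  site) anneals toward a single global orientation; it does not produce
  the grain-boundary dynamics of real lattices, which is why grains are
  injected explicitly in the scene generator instead.
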