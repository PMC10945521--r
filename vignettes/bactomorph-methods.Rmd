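---
title: "Models and methods behind bactomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bactomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

bactomorph bundles the four quantitative analyses that recur in studies of
bactofilin/M23-peptidase cell-shape control: a displacement-mixture model
for single-particle tracking, medial-axis-based cell profiling, a
gene-neighborhood screen, and steady-state binding/growth fits. This
vignette is the package's own account of those methods: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-data generators do and do not emulate, and
the numerical choices a maintainer would want written down.

# The two-population displacement mixture

## Model

Tracked single molecules are assumed to belong to one of two states: a
*static* state (polymer-bound; small residual apparent motion) and a
*mobile* state (free diffusion). For a molecule diffusing with coefficient
*D*, each per-axis frame-to-frame displacement over interval Δt is
Gaussian with mean zero and variance 2·D·Δt. Pooling the x and y
components of every consecutive-frame step of every track (both appended
as separate scalar samples) therefore yields a two-component, zero-mean
Gaussian mixture:

  p(x) = f·N(x; 0, σ_s²) + (1 − f)·N(x; 0, σ_m²),  D_i = σ_i²/(2Δt)

with f the static fraction. The model is *stateless over displacements*:
it does not track which molecule produced which step, and it assumes no
state switching within the pooled sample (switching only broadens the
components).

Key assumptions, and where they can bite:

* **Unit frame separation.** Displacements across frame gaps are excluded
  (no gap closing): a two-frame gap would have variance 4·D·Δt and
  contaminate the mixture. `pooled_displacements()` enforces this.
* **Apparent coefficients.** Localization error σ_loc adds 2·σ_loc² to
  every observed squared displacement, so the fitted D values are
  *apparent*. The static coefficient in particular (≈0.02 µm²/s at 30 ms
  framing) is of the same order as a typical localization error and
  should be read as an upper bound on true polymer mobility. By default
  the package reports apparent values; passing `localization_sd` to
  `fit_two_population()` subtracts σ_loc²/Δt from both coefficients when
  σ_loc is known independently.
* **Pooled scalars, not 2D vectors.** x and y displacements are treated
  as exchangeable scalar samples. A joint 2D fit would weight each step
  once instead of twice; for isotropic diffusion the point estimates are
  the same, only nominal standard errors differ (bootstrap intervals are
  available via `bootstrap = n`).

## Estimation

The mixture is fitted by expectation–maximization with deterministic,
scale-free initialization: σ starting values come from the 25th and 90th
percentiles of |x| (rescaled by half-normal quantiles), weights start at
0.5/0.5. Convergence is declared when the relative log-likelihood change
drops below 1e-9, with a 1,000-iteration cap — deliberately conservative,
because component separation σ_m/σ_s ≈ 4 at the default regimes leaves a
shallow likelihood near the optimum. The M-step keeps σ above a floor of
max(1e-8, 1e-6·sd(x)) to avoid the classic variance-collapse singularity.

Labelling: the smaller-σ component is called static; near-exact ties are
broken by weight (the heavier component is called static). An all-zero
sample short-circuits to f = 1, D_static = 0 with a `degenerate` flag; a
fit in which one weight falls below 0.5% or the two σ agree to 0.1% is
flagged near-degenerate rather than silently reported.

The test suite checks the EM against an independent dense grid search
over (f, σ_s, σ_m) maximizing the same likelihood on small samples, and
checks parameter recovery on simulations: the defaults recover a static
fraction to within ±0.03 and D values to within ±10% at 20,000 pooled
displacements.

`--fix-static-d` semantics are provided by the `fix_static_d` argument
(the static σ is held at √(2·D·Δt) during the M-step), for users who
prefer the convention of fixing the bound-state coefficient.

## MSD and heat maps

`msd_curve()` uses the time-averaged-then-ensemble-averaged estimator:
per track, the mean squared displacement over all position pairs exactly
k frames apart; then the across-track mean, with the across-track
standard deviation as the spread. The default maximum lag,
min(10, ⌊shortest-track/4⌋), is the usual bias/variance compromise —
long lags on short tracks average very few pairs. `localization_heatmap()`
is a plain 2D position histogram; its only parameter is the bin size
(default 0.05 µm, i.e. half a camera pixel at 100 nm/px).

# Cell geometry and curve profiles

## Medial axis

`extract_geometry()` computes the axis in five deterministic steps:
Zhang–Suen thinning of the mask; reduction to the longest geodesic path
through the skeleton graph (8-connectivity, Euclidean weights), which
also removes side spurs; trimming of 1.5× the cell half-width from each
path end (the skeleton of a band runs diagonally into the pole corners
for about one half-width — those branches carry no axis information);
running-mean smoothing (window 7 px) to suppress the raster staircase;
and re-extension of each end to the cell pole along a circular arc whose
curvature and heading are fitted to the last ~14 px of the path. The arc
extension matters: a straight tangent ray systematically exits a curved
cell ~2 px outside the cap centre, which inflates the pole-to-pole chord
and biases sinuosity low.

A mask whose axis is shorter than 1.2× its width (e.g. a disk) is
rejected with a degenerate-axis error rather than silently producing an
arbitrary axis. Masks must be a single connected component without holes.

## Inner/outer split and labelling

`split_edges()` classifies every outline vertex by the side of the medial
axis it falls on (sign of the cross product with the local axis tangent),
after trimming half a cell width off each axis end so the pole caps are
claimed by neither edge. The two longest constant-side runs are the edge
paths.

Labels are assigned by the **total signed turn of the axis** (tangent
angles summed over ~10-sample baselines): the concave side — the side the
axis turns toward — is the inner curve. We chose curvature over the more
obvious arc-length comparison because at raster resolution the two edge
paths of even a perfectly straight cell differ by 2–3 px from contour
quantization, which rivals the true inner/outer difference of mildly
curved cells. An axis turning by less than 0.2 rad (~11°) is treated as
straight: the result is flagged `symmetric_flagged`, a warning is raised,
and labels fall back to the (then arbitrary but deterministic) arc-length
order. Mirroring a cell flips both the turn sign and the side signs, so
the same physical edge stays labelled inner.

## Profiles, enrichment, demographs

`edge_profiles()` and `axis_profile()` resample their path to `n_points`
equally spaced in arc length and average image pixels within
`band_width_px` (default 3 px) of each sample, restricted to the cell
mask. The 3-px band is a compromise: wide enough to average shot noise,
narrow enough that on a 10-px-wide cell the inner band does not bleed
into the outer half. Inner-curve enrichment is mean(inner)/mean(outer).

`concat_profile()` joins outer-then-inner with the transition index
recorded — the column marked by the dashed line in curved-cell
demographs. `build_demograph()` min–max normalizes each profile within
its cell (an all-constant profile maps to 0.5 and is flagged), sorts rows
by cell length ascending, and registers cells either at midcell
(`align = "pole"`, for straight-cell demographs) or at the outer→inner
transition (`align = "transition"`). Per-cell normalization is the
default because absolute intensities vary with expression level;
`normalize = FALSE` preserves a global scale.

Sinuosity is centerline arc length divided by the pole-to-pole Euclidean
chord, computed on the medial axis (not the boundary, and not a
Feret-based ratio — the centerline definition is the one that is exact on
analytic test shapes: 1 for a straight axis, π/2 for a semicircle).
Pearson colocalization is the standard correlation over mask pixels, and
errors (rather than returning 0) on zero-variance channels.

# The gene-neighborhood screen

"Immediately upstream or downstream" is interpreted as **rank adjacency**:
genes are ordered by start coordinate within each replicon, and a pair is
emitted whenever a bactofilin-family gene and an M23-family gene occupy
adjacent ranks — in either order and on any strand combination.
Orientation (co-directional / convergent / divergent) is reported, never
filtered on, because operon-like, convergent and divergent arrangements
are all biologically informative. A single gene annotated with both
families never pairs with itself; every unordered pair is emitted once;
the output is independent of input row order.

Coordinates are 1-based inclusive (GFF3), and the one distance formula
used everywhere is `g2.start − g1.end − 1`, so 0 means abutting genes and
−17 a 17-bp overlap — the arrangement characteristic of tightly coupled
bactofilin/peptidase operons. Domain assignment consumes an external
hit table (protein_id, family, e-value) with an inclusive cutoff,
default 1e-5 — domain detection itself is out of scope, and the default
is the conventional screening threshold rather than a tuned value.
Adjacency across a circular replicon's origin is off by default
(`circular = TRUE` enables it): annotation tables rarely order
origin-spanning genes reliably.

`summarize_screen()` deduplicates to species (a species counts once no
matter how many genomes or pairs support it) and aggregates lineage
strings at a configurable rank, default phylum. `export_itol()` writes a
COLORSTRIP dataset file; `read_itol()` round-trips it.

# Binding and growth fits

`fit_one_site()` fits R(C) = Rmax·C/(K_D + C) by Levenberg–Marquardt
least squares with both parameters constrained positive. Initialization
is deterministic and data-driven: K_D starts at the concentration whose
response is nearest half of the maximum (falling back to the median
concentration), Rmax at the maximum response. A reference-sensor column
is subtracted point-wise before fitting; all-zero responses raise a "no
specific binding" error instead of fitting noise. The test suite holds
the optimizer to a dense 2D grid search on small series and to exact
(≤1e-6 relative) recovery on noiseless data.

`simulate_kinetic_trace()` provides the closed-form 1:1 association and
dissociation curves (plateau R_eq = Rmax·C/(K_D + C) with
K_D = k_off/k_on); its steady-state plateaus feed `fit_one_site()` in a
cross-module consistency test.

`fit_growth()` takes µ as the slope of the least-squares line through
ln(OD) versus time within a user-stated window and reports
t_d = ln(2)/µ — i.e. µ is the exponential rate constant, the only
definition consistent with that doubling-time identity (a literal
"increase in OD per hour" would not be). Slopes below 1e-12 h⁻¹ are
treated as non-positive and leave t_d undefined with a flag. Because
window choice is a judgment call on real curves, `suggest_growth_window()`
proposes the span whose log-linear fit maximizes R².

# Synthetic data: what it emulates, and what it does not

The generators produce inputs with exactly the statistical structure the
estimators assume, with every random draw governed by an integer seed
(fixed seed ⇒ bit-identical output):

* `simulate_tracks()` — two-state Brownian tracks at Δt = 0.03 s (the
  default mirrors 30 ms acquisition). Tracks are assigned static or
  mobile identity by a Bernoulli draw; by default molecules do not switch
  state within a track, matching the mixture model's assumptions; a
  two-state Markov switching mode (`switching = list(k_on=, k_off=)`)
  exists but is off by default. Track lengths default to a fixed 20 steps
  (sharp recovery tests); a geometric-length option crudely models
  photobleaching. Localization noise is added to *positions*, so
  consecutive observed displacements are negatively correlated, as in
  real data. Optional confinement (rectangle or spherocylinder) uses
  specular reflection, the simplest rule that preserves step statistics
  away from walls. Defaults for the recovery regimes (D = 0.02 and
  0.35 µm²/s; fractions 0.6/0.7/0.8/0.1; 500 tracks × 20 steps = 20,000
  pooled displacements) are the documented study conditions.
* `render_curved_cell()` — an arc-shaped band of constant width with
  uniform channel A and a channel B whose inner (concave) half is
  brighter by a chosen factor, plus Gaussian read noise. It does **not**
  model a PSF, uneven illumination, neighboring cells or segmentation
  error, so passing recovery tests demonstrates the correctness of the
  geometry pipeline, not robustness to those real-data effects.
* `generate_genomes()` — rank-ordered gene tables with planted adjacent
  bactofilin/M23 pairs at a prescribed orientation and intergenic
  distance (default −17 bp, co-directional), screen-negative genomes with
  the two families separated by intervening genes, and decoy families
  elsewhere. Gene lengths (300–1500 bp) and intergenic gaps (50–200 bp)
  are uniform draws — typical bacterial scales, chosen once.
* `simulate_binding()` / `simulate_growth()` — the hyperbolic and
  exponential models plus Gaussian noise.
* No photophysics beyond track-length truncation, no 3D diffusion, no
  camera model anywhere.

# Problem sizes and numerical conventions

The shipped tests run the mixture recoveries at 20,000 pooled
displacements per regime (with a 20-replicate median-error check), MSD
linearity at 2,000 tracks, enrichment recovery at 100 rendered cells per
enrichment level (e ∈ {1.0, 1.5, 2.0}, varied radii/angles/widths), and
the screen on 30–50 planted genomes — sizes chosen so the whole suite
runs in a couple of minutes on one CPU while keeping Monte-Carlo error
well inside the asserted tolerances.

Conventions: image coordinates are (row, col) with pixel centres at
integers; physical lengths come from `pixel_size` (µm/px); masks are 0/1
matrices; all diffusion quantities are µm and seconds; concentrations µM;
responses nm; growth times hours. Configuration files are flat
`key = value` text (`run_config()`), and `run_pipeline()` writes an MD5
manifest so identical configs are verifiably identical runs.

# Known limitations

* The mixture model fixes exactly two zero-mean components; anomalous
  diffusion, drift, or more than two states will be absorbed into the
  two σ values without diagnostic warning beyond fit flags.
* Medial-axis accuracy degrades on cells shorter than ~3× their width;
  such cells tend to fall under the 0.2-rad near-straight flag, and
  their inner/outer labels should not be trusted (they are flagged,
  not suppressed).
* The screen trusts its input annotation: unannotated ORFs make two
  genes look adjacent that are not, and split genes break rank
  adjacency. Recall/precision of 1.0 holds on planted tables, not on
  noisy real annotations.
* `fit_growth()` assumes the window is exponential; it will happily fit
  a log-linear slope through lag or stationary phase if told to.
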