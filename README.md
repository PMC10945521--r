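# bactomorph

Quantitative analyses for studies of bactofilin-driven cell-shape control
in budding and spiral-shaped alphaproteobacteria. Bactofilins are
self-polymerizing cytoskeletal proteins; in several species their genes sit
immediately next to genes for M23 peptidases (cell-wall DD-endopeptidases),
and the two proteins jointly position cell-wall growth. Testing that model
quantitatively requires four very different analyses, which this package
implements as one tidyverse-style toolkit:

1. **Single-particle diffusion** — pooled frame-to-frame displacements of
   tracked molecules are fitted with a two-component, zero-mean Gaussian
   mixture. For component *i* with standard deviation σᵢ over per-axis
   displacements at frame interval Δt, the apparent diffusion coefficient
   is *D*ᵢ = σᵢ²/(2Δt); the weight of the small-σ component is the **static
   (polymer-bound) fraction**. MSD-versus-lag curves (MSD(τ) ≈ 4*D*τ for
   free 2D diffusion) and localization heat maps support the fit.
2. **Cell geometry** — medial-axis extraction from binary cell masks;
   fluorescence profiles along the medial axis or along the outer and
   inner curve of bent cells; demographs (per-cell profiles, min–max
   normalized, sorted by cell length); sinuosity (axis arc length /
   pole-to-pole chord); Pearson colocalization of two channels.
3. **Gene-neighborhood screen** — finds genomes in which a bactofilin-domain
   gene is rank-adjacent to an M23-peptidase-domain gene, classifies each
   pair (orientation; intergenic distance, negative = overlap), summarizes
   at the species/taxon level and exports iTOL annotations.
4. **Binding and growth** — one-site steady-state fit
   *R*(C) = *R*ₘₐₓ·C/(K_D + C) for bio-layer interferometry ladders, and
   exponential growth fits with *t*_d = ln(2)/µ.

Every stage has a seeded synthetic-data generator (`simulate_tracks()`,
`render_curved_cell()`, `generate_genomes()`, `simulate_binding()`,
`simulate_growth()`) that emulates its input with known ground truth, so
each estimator is validated by parameter recovery rather than by eye.

## Worked example: static and mobile molecule populations

Simulate tracking data for a protein that is 70% polymer-bound
(D = 0.02 µm²/s) and 30% freely diffusing (D = 0.35 µm²/s), imaged at
30 ms per frame, then recover those parameters:

```r
library(bactomorph)

ts   <- simulate_tracks(n_tracks = 500, steps_per_track = 20,
                        d_static = 0.02, d_mobile = 0.35, f_static = 0.7,
                        frame_interval = 0.03, seed = 42)
kept <- filter_tracks(ts, min_steps = 5)
fit  <- fit_two_population(pooled_displacements(kept))
fit
#> Two-population displacement mixture fit
#>   static: f = 0.708, D = 0.0207 um^2/s
#>   mobile: f = 0.292, D = 0.3591 um^2/s
#>   logLik = 25261.19 | n = 20000 | converged
```

The fit recovers the simulated static fraction (0.708 vs 0.70) and both
diffusion coefficients (0.0207 vs 0.02; 0.359 vs 0.35 µm²/s) from 20,000
pooled displacements. `glance(fit)` returns the same numbers as a one-row
tibble, `tidy(fit)` one row per component, and `autoplot(fit)` overlays
the fitted mixture density on the displacement histogram.

The MSD curve of the same data is linear in lag, as expected for a
Brownian mixture:

```r
msd_curve(kept, max_lag = 5)
#> # A tibble: 5 × 4
#>   lag_s msd_um2 sd_um2     n
#>   <dbl>   <dbl>  <dbl> <int>
#> 1  0.03  0.0143 0.0191   500
#> 2  0.06  0.0288 0.0392   500
#> 3  0.09  0.0431 0.0600   500
#> 4  0.12  0.0579 0.0827   500
#> 5  0.15  0.0729 0.107    500
```

A binding ladder fits the same way:

```r
fit_one_site(simulate_binding(kd = 15, rmax = 1.2, noise_sd = 0.02, seed = 1))
#> One-site binding fit: KD = 15.1 uM (SE 0.71), Rmax = 1.21 nm (SE 0.016)
```

Other entry points follow the same pattern: `extract_geometry()` →
`split_edges()` → `edge_profiles()` → `concat_profile()` →
`build_demograph()` for imaging data; `assign_domains()` → `find_pairs()`
→ `summarize_screen()` → `export_itol()` for the genomic screen;
`run_pipeline(run_config(...))` chains stages from one seeded
configuration and writes a digest manifest.

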