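# puncta

Quantitative analysis of fluorescent puncta in 2D time-lapse microscopy,
for researchers tracking intracellular particles — protein aggregates,
vesicles, lysosomes — and asking *how* they move and *what* they touch.

The package implements the full chain from raw frames to population
statistics:

* **Detection** — difference-of-Gaussians (DoG) blob detection with
  sub-pixel, noise-floored centroid refinement and a normalized quality
  scale;
* **Tracking** — two-pass LAP (linear assignment problem) linking:
  optimal frame-to-frame matching plus gap closing between track
  segments, solved exactly by shortest augmenting paths;
* **Motion analysis** — per-trajectory time-averaged MSD, a weighted fit
  of `MSD(Δt) = 4DΔt + v²Δt²` with a Monte-Carlo-calibrated test for
  directed transport, the anomalous exponent α from a log–log fit, and
  classification into constrained (α < 0.8), diffusive, or transported
  (α ≥ 1.5) motion;
* **Morphometrics** — Otsu segmentation, chain-code perimeters,
  circularity `4πA/P²`, per-cell mean grey values, and the percentage of
  cells containing at least one aggregate;
* **Colocalization kinetics** — splitting organelles into colocalized
  (CL) vs non-colocalized (NCL) populations against a second channel,
  tracking both, and comparing displacement, speed and size with Welch's
  t test;
* **Synthetic ground truth** — a movie generator (Brownian / directed /
  confined motion, pixel-integrated Gaussian PSF, Poisson + read noise,
  two-channel colocalization) so every stage is validated against known
  parameters.

See the methods vignette (`vignettes/motion-analysis.Rmd`) for the
models, the statistical choices and their rationale.

## Worked example

Simulate nine particles — three per motion class — image them at 1
frame/s for 60 s, and analyse their trajectories:

```r
library(puncta)

sim <- simulate_ensemble(
  list(motion_model("brownian", D = 0.05, sigma_loc = 0.02),
       motion_model("directed", D = 0.01, v = c(0.3, 0), sigma_loc = 0.02),
       motion_model("confined", D = 0.05, R = 0.5, sigma_loc = 0.02)),
  n_particles = 9, n_frames = 60, dt = 1, seed = 7)

fits <- analyze_motion(sim$tracks, fit_range = 20)
fits[, c("track_id", "D", "v", "directed_flag", "alpha", "motion_class")]
#>   track_id      D     v directed_flag  alpha motion_class
#> 1        1 0.0349 0.000         FALSE 0.8992    diffusive
#> 2        2 0.0115 0.315          TRUE 1.8997  transported
#> 3        3 0.0169 0.000         FALSE 0.0861  constrained
#> 4        4 0.0410 0.000         FALSE 0.8548    diffusive
#> 5        5 0.0120 0.290          TRUE 1.8553  transported
#> 6        6 0.0168 0.000         FALSE 0.0972  constrained
#> 7        7 0.0448 0.000         FALSE 0.8304    diffusive
#> 8        8 0.0063 0.312          TRUE 1.9224  transported
#> 9        9 0.0131 0.000         FALSE 0.3268  constrained

summarize_motion(fits)$fractions
#> constrained   diffusive transported
#>   0.3333333   0.3333333   0.3333333
```

Each row is one trajectory: `D` is the fitted diffusion coefficient
(µm²/s), `v` the fitted transport speed (µm/s; the three directed tracks
recover speeds near the simulated 0.3 µm/s and are the only ones flagged
directed), `alpha` the log–log MSD slope, and `motion_class` the
resulting label — here all nine tracks classify correctly, giving equal
thirds.

The same functions apply to real data: `read_movie()` a multi-page TIFF,
`detect_movie()`, `link_tracks()`, `filter_trajectories()`, then
`analyze_motion()`. `run_pipeline()` executes the whole chain (including
the two-channel CL/NCL comparison) from a `pipeline_config()` and writes
CSV tables plus a JSON report, all carrying the configuration hash. A
thin command-line front end with `simulate` / `detect` / `track` / `msd`
/ `run` verbs is installed at `inst/cli/puncta`.

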