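# paintbench

Quantitative benchmarking of fluorescent dyes for DNA-PAINT
single-molecule localization microscopy, as a reusable, tested R pipeline.

In DNA-PAINT, a dye-labeled *imager* oligonucleotide transiently
hybridizes to a target-bound *docking* strand. Every bound period appears
as a run of consecutive-frame localizations, so one measurement of a field
of DNA-origami docking sites carries far more than an image: it encodes
the dye's photon output, its binding kinetics, its signal-to-background
ratio, the slow photo-destruction of docking strands, and its off-target
sticking. `paintbench` implements both the *readout* of these quantities
and a *generative simulator* of the blinking data, so that every estimator
can be validated against known ground truth without any microscope.

## The quantities

For a docking site observed over a measurement of duration `T` with frame
time `Δ` (default 100 ms):

- **Binding events** — maximal runs of consecutive-frame localizations
  (`link_events`). Bright/dark times per site come from least-squares fits
  of `F(t) = 1 − a·exp(−t/τ)` to the empirical CDF of the observed
  durations (`fit_mean_time`); the free amplitude absorbs the distortion
  that camera discretization imposes on the shortest durations, so `τ` is
  recovered without discretization bias.
- **Photons per 100 ms** — the mean photon count of *center frames* only:
  frames of events ≥ 3 frames long that are neither first nor last
  (`center_frame_photons`). First/last frames under-count photons because
  binding and unbinding rarely coincide with frame boundaries; the naive
  all-frame mean is biased low.
- **SBR** — the fitted PSF integrated over a 1×1 px square at its maximum,
  `N·erf(1/(2√2 sx))·erf(1/(2√2 sy))`, divided by the per-pixel
  background offset (`compute_sbr`).
- **Destruction statistic** — per site, `r = t_end/τ_d` where `t_end` is
  the time from the last recorded event to the end of the measurement.
  For intact, stationary sites `r ~ Exp(1)`; an exponential
  `a·exp(−r/μ)` fitted to the `r` histogram must give `μ = 1`, and the
  percentage of sites with `r > 4μ`, minus the `100/e⁴ = 1.83%` tail an
  intact population itself produces, estimates the destroyed-site
  percentage (`destruction_statistic`).
- **Localization precision** — per localization via the Mortensen
  closed form `σ² = (s_a²/N)(16/9 + 8π s_a² b/(N a²))`, `s_a² = s² + a²/12`
  (`mortensen_sigma`); per measurement via NeNA, fitting the
  nearest-neighbour distance distribution between adjacent frames
  (`nena_sigma`).
- **Specificity, structures, channels** — density-based site clustering
  (`cluster_smlm`), five-cluster crosshair origami identification
  (`find_crosshairs`), region-based relative specificity that cancels
  imager-concentration bias (`relative_specificity`), affine channel
  registration and cross-talk (`fit_affine`, `crosstalk`), spot detection
  and pixel-integrated Gaussian fitting for raw movies (`detect_spots`,
  `fit_spot`).

The simulator (`sim_config` + `emit_localizations`) draws two-state
exponential binding kinetics, partial-frame Poisson photon collection,
Poisson background, Mortensen-limited localization jitter, per-site
destruction, exponentially decaying effective on-rate, uniform sticking,
and origami-grid / crosshair / nuclear-pore site geometries; `render_movie`
produces raw photon-count TIFF stacks.

## Worked example

Simulate a Cy3B-grade dye (bright time 0.35 s, 23,195 photons per 100 ms,
dark time 10 s) on 500 isolated docking sites for 500 s, then run the full
analysis:

```r
library(paintbench)

cfg <- sim_config(tau_b = 0.35, tau_d = 10, n_frames = 5000,
                  photon_rate = 23195, bg_rate = 238,
                  width = 128, height = 128,
                  layout = layout_single_sites(500, 128, 128), seed = 42)
sim <- emit_localizations(cfg)
res <- analyze_origami(sim$locs, min_sites = 100)
print(res$summary, digits = 3)
#>   precision_nm photons_per_100ms bright_time_s  sbr loc_drop_pct destroyed_pct
#> 1         1.51             23118         0.348 14.2         3.39          1.08
print(res$destruction)
#> Destruction statistic: mu = 1.075, destroyed = 1.08% (raw tail 2.91% - 1.83%) over 481 sites
```

Reading the row: the pipeline recovers the generative photon rate (23,118
vs. 23,195) and bright time (0.348 vs. 0.35 s); the SBR of 14.2 follows
from the photon rate, PSF width and background; the destruction fit
calibrates to `mu ≈ 1` with a destroyed-site percentage near zero, as it
must for a simulation with no destruction; and the NeNA precision of
1.5 nm is the Mortensen limit at these photon counts (a real microscope
adds residual drift and vibration on top). `summarize_repeats()` turns
several such rows into mean ± sd benchmark entries.

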