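---
title: "Benchmarking DNA-PAINT dyes: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking DNA-PAINT dyes: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The generative model

DNA-PAINT blinking at a single docking site is modelled as an alternating
renewal process: the site is unbound for an exponential dark time with
mean `tau_d`, then bound for an exponential bright time with mean `tau_b`,
and so on. The process starts unbound with a fresh dark time; by
memorylessness of the exponential this is equivalent to a stationary
start, so no burn-in is needed. On top of this two-state kinetic skeleton
the simulator layers the measurement physics:

- **Partial-frame photon collection.** A camera frame overlapped by a
  bound period for a fraction `f` of its exposure collects
  `Poisson(photon_rate * (exposure / 0.1) * f)` photons, where
  `photon_rate` is the expected photon yield of a fully bound imager in
  100 ms. First and last frames of an event therefore under-count photons
  — the effect the center-frame estimator exists to remove. If the dark
  gap between two events is shorter than a frame, the camera integrates
  both; the simulator merges such same-frame records exactly as a camera
  would (sums of independent Poisson counts are Poisson).
- **Localization jitter.** Each frame-localization is displaced from the
  true site position by an isotropic Gaussian whose standard deviation is
  the Mortensen precision at that localization's photon count, the
  per-pixel background, and the PSF width. Poisson photon noise is the
  only noise model; camera gain, offset and read noise are out of scope.
- **Docking-site destruction.** Each site is destroyed with probability
  `destroy_fraction`, at a time drawn uniformly over the acquisition
  (`destroy_timing = "uniform"`) or at t = 0 (`"start"`, for structure
  completeness experiments). No events start after destruction.
- **On-rate decay.** Partial photodamage to concatenated docking
  sequences lowers the effective imager on-rate without killing the site.
  This is modelled as a single exponential: the instantaneous binding
  rate is `(1 / tau_d) * exp(-onrate_decay * t)`. One parameter suffices
  to produce a testable, quantifiable localization drop.
- **Sticking.** Off-target localizations appear uniformly in the field at
  `sticking_density` per µm² per frame, last one frame, and carry a
  uniform partial-frame photon fraction.
- **Geometry.** Layouts place isolated single sites, 3 × 4 origami grids
  with 20 nm spacing, five-site crosshairs (one central dye-of-interest
  site plus four barcode arms), or eightfold-symmetric rings of site
  pairs mimicking the nuclear pore scaffold. Coordinates are continuous
  pixels, origin at the top-left pixel corner, 130 nm pixels by default.

All randomness flows from one integer seed; identical configurations
yield byte-identical localization tables.

What the simulator does **not** emulate: stage drift, dye photophysics
within a bound period (triplet blinking, photobleaching of the imager),
astigmatic 3D PSFs, camera noise, and spatially structured sticking in
cells. Consequently, passing recovery tests here demonstrates estimator
correctness under the stated statistical model — not robustness to drift
or non-Poisson cameras, which real pipelines handle in separate
correction steps.

## Estimators and their numerical choices

### Bright and dark times

Durations are observed in whole frames: an event's bright duration is its
frame count times the exposure; a dark duration is the frame gap between
consecutive events times the exposure (the lead-in before a site's first
event is not a dark time). The mean time is fitted by least squares of

```
F(t) = 1 - a * exp(-t / tau)
```

to the empirical CDF evaluated at the observed durations (unique values,
weighted by multiplicity). The amplitude `a` is deliberately free: for
exponentially distributed true durations observed on a frame lattice, the
survival function at the observed support is *exactly* `a' * exp(-t/tau)`
for some `a'` that differs from 1, so the two-parameter fit recovers
`tau` without discretization bias, while on continuous data it reduces to
the one-parameter fit and agrees with the sample-mean MLE to within a few
percent. Sites with fewer than `min_events = 10` durations, or with
degenerate (all-identical) durations, are excluded and flagged rather
than fitted. The measurement value is the unweighted mean of the per-site
fits; weighting sites by event count is a defensible alternative, but the
unweighted mean treats each physical docking site as one unit of
evidence, which matches how per-site statistics are reported throughout.

### Center-frame photons and SBR

Only frames of events at least three frames long that are neither first
nor last measure a continuously bound imager; their counts, scaled by
`0.1 / exposure`, estimate photons per 100 ms. The estimator is invariant
to the exposure chosen, which the test suite checks at 50, 100 and
200 ms. The SBR integrates the *unit-mass* fitted PSF over a 1 × 1 px
square centered at its maximum — `erf(1/(2*sqrt(2)*sx)) *
erf(1/(2*sqrt(2)*sy))` — multiplies by the photon count and divides by
the per-localization fitted background offset. Using the per-localization
background (not a global average) keeps the ratio meaningful when the
background drifts across a measurement. Localizations with non-positive
background are excluded.

### The destruction statistic

For each site the gap `t_end` from the end of its last event to the end
of the measurement is divided by its own CDF-fitted mean dark time. For
intact, stationary sites this ratio is a sample from Exp(1) — the wait
from an arbitrary cutoff back to the previous renewal of a memoryless
process — so an exponential `a * exp(-r / mu)` fitted to the histogram of
all ratios must give `mu = 1`; values above 1 signal decaying sampling.
The destroyed-site percentage is the fraction of sites beyond `4 * mu`
minus `100 / e^4` (1.83%), the tail an intact population itself places
there, clamped at zero.

Three numerical choices deserve explanation:

- **Censoring.** A site whose last event is still running in the final
  frame is observed alive at the cutoff: its gap time is undefined and it
  is trivially not destroyed. Such sites are censored (`r = NA`) rather
  than assigned `r = 0`. With realistic dye kinetics the bound fraction
  is 1–3% and the choice is numerically irrelevant, but assigning zeros
  would put a spurious atom in the first histogram bin and drag the
  fitted `mu` well below 1.
- **Binning.** Fixed width 0.25 over `[0, max(10, max r)]`. The fit uses
  all bins up to the last occupied one, *including* interior empty bins:
  fitting only non-empty bins would keep upward tail fluctuations and
  discard the zeros between them, inflating `mu`.
- **Lattice effects.** `t_end` is a whole number of frames, so `r` lives
  on a lattice of spacing `exposure / tau_d`. If the dark time is only a
  few seconds at 100 ms frames, that lattice (0.025–0.05) beats against
  the 0.25 bin width and distorts the fit by up to 10%. Calibration runs
  therefore use a dark time of 10 s — a realistic single-docking-site
  value at typical imager concentrations — where the lattice is fine
  (0.01) and the distortion vanishes. This is a property of the
  histogram-fit procedure itself, inherited faithfully; the package keeps
  the procedure rather than replacing it with a tail-robust alternative.

The sampling noise of the histogram fit is substantial at moderate site
counts (sd of `mu` is about 0.08 at 500 sites, 0.04 at 1,800), so the
calibration experiment in `scripts/acceptance.R` uses 2,000 sites
observed for 75 dark times; measured across seeds this yields
`mu = 1.00 ± 0.02`.

### Localization precision

The Mortensen closed form gives per-localization precision from photons
`N`, per-pixel background `b`, PSF width `s` and pixel size `a`:

```
sigma^2 = (sa^2 / N) * (16/9 + 8 * pi * sa^2 * b / (N * a^2)),
sa^2 = s^2 + a^2 / 12
```

NeNA estimates the *measurement-level* precision from nearest-neighbour
distances between localizations in adjacent frames. The same-emitter term
is the 2D distance distribution of the difference of two isotropic
Gaussians of width sigma — hence `d/(2 sigma^2) * exp(-d^2/(4 sigma^2))`
— mixed with a linear false-pair term `2d / W^2` normalized over the
search window `W` (1 px default). The mixture is fitted to a binned
distance histogram (0.02 px bins; the binning refines automatically when
all distances are far below one bin, so near-zero jitter is resolved
instead of railing at the bin width). The linear correction term is the
simplest density model for false pairs and is isolated in one place so a
different correction can be swapped in. On simulator output NeNA agrees
with the photon-weighted mean Mortensen sigma to within 15% across photon
rates from 2,000 to 23,000 per 100 ms; the photon weighting is the right
comparison because dim partial frames contribute correspondingly little
to the pair distances.

### Clustering, crosshairs, specificity

The site clusterer is a density scheme with the two standard parameters
(radius 0.04 px ≈ 5 nm, minimum 15 localizations): a localization is a
core point if at least `min_locs` localizations (itself included) fall
within `radius`; clusters are connected components of core points plus
their in-radius neighbours. Border points touching several clusters go to
the cluster of smallest id after a canonical (x, y) sort, which makes the
output independent of input order — verified against a brute-force
O(n²) oracle. Crosshair origami are accepted only with exactly five
clusters (complete, correctly folded structures); the dye-of-interest
site is the cluster nearest the pick center plus a configurable offset,
central by default. Relative specificity divides signal-per-area over
background-per-area in the imaging round by the same ratio in the
reference round on *identical* regions, cancelling imager concentration
and shared off-target effects; circular picks use strict interior
membership (boundary points are outside) and analytic areas, masks use
pixel-count areas.

### Spot detection and fitting

Detection finds strict local maxima whose *net gradient* — the sum over
the box of the intensity gradient projected toward the box center —
exceeds a threshold; the threshold is a per-measurement input, as it is
in practice. Fitting minimizes least squares of an offset plus a 2D
Gaussian *integrated over pixels* via CDF differences (never
point-sampled), initialized at the brightest pixel with the PSF prior;
non-converged fits are flagged and excluded downstream. On noiseless
rendered spots the fit recovers centers to 10⁻³ px and photon mass to 1%;
on Poisson-noise spots the empirical scatter matches the Mortensen
prediction within 20%.

## Problem sizes

The test suite validates estimators at the smallest sizes that leave the
statistical tolerances meaningful: hundreds of sites and 1–2 thousand
frames for kinetic recoveries, 2,000 sites for the destruction
calibration, 100–200 Monte-Carlo repeats for fit-coverage checks. These
sizes are choices about statistical resolution, and the tolerances in the
tests are derived from the corresponding standard errors.

## Known limitations

- The destruction estimator's accuracy degrades when destruction happens
  so early that a site never accumulates `min_events` dark times; such
  sites are excluded, slightly under-counting very early destruction.
- The localization drop is defined as first-versus-last 20 s window of
  the per-site localization rate; other windowings are defensible and
  would give somewhat different percentages on decaying measurements.
- NeNA's false-pair term is linear in distance; in very dense fields a
  measured pair-correlation term would be more faithful.
- The simulator's sticking is spatially uniform; cellular data with
  structured background should be represented through region masks, not
  through the sticking model.
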