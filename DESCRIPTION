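Package: paintbench
Title: Simulation and Kinetic Benchmarking of DNA-PAINT Dye Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark fluorophore performance in DNA-PAINT
    single-molecule localization microscopy. Provides a generative simulator of
    DNA-PAINT blinking data (two-state exponential binding kinetics,
    partial-frame photon collection, Poisson photon and background emission,
    Mortensen-limited localization jitter, docking-site destruction, decaying
    effective on-rate, unspecific sticking, DNA-origami and nuclear-pore site
    geometries), plus the estimators used to grade dyes: binding-event linking,
    cumulative-distribution bright/dark-time fits, center-frame photon counts,
    pixel-integral signal-to-background ratio, sampling-stability traces, a
    docking-site destruction statistic, Mortensen and nearest-neighbor (NeNA)
    localization precision, density-based site clustering, crosshair structure
    identification, region-based relative specificity, and multi-channel
    affine registration with cross-talk quantification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
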