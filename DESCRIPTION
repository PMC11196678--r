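Package: macrocast
Title: Forecasting Global Marine Macrophyte Distributions Under Climate Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for forecasting the distribution
    of marine macrophytes (canopy-forming brown macroalgae and seagrasses)
    under greenhouse-gas emissions scenarios. Builds per-species extents of
    occurrence from point records with an iterative alpha-hull procedure, fits
    random-forest habitat-suitability models with equal-size pseudo-absence
    sampling and iterative variable elimination, projects yearly suitability
    maps to 2100, and derives stacked-SDM species diversity, thresholded
    habitat-extent and area-of-occupancy trajectories. A virtual-species world
    generator (scenario-driven environmental layers, known Gaussian niches,
    biased occurrence sampling) provides ground truth so every stage of the
    pipeline is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
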