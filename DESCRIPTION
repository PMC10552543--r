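Package: shoredye
Title: Wave-Driven Nearshore Alongshore Tracer Transport, Decay, and
    Beach-Advisory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-dimensional model of wave-driven alongshore transport and
    decay of a shoreline pollution tracer, for dry-weather coastal water
    quality assessment. Converts offshore wave buoy bulk parameters
    (significant wave height, peak period, direction) into a surf-zone
    alongshore current via linear wave theory and a linearized bottom-stress
    balance, solves the 1D advection-loss equation for tracer concentration
    with physical export and biological inactivation rates, and provides
    calibration routines (drag coefficient, loss rate, source concentration),
    model-skill metrics (Pearson correlation, normalized RMSE, Willmott skill
    score), and beach-advisory decision analysis (threshold exceedance,
    sensitivity/specificity, simulated weekly water-quality sampling).
    Includes a seeded synthetic wave-climate and reference-field generator so
    the full workflow runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
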