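Package: pulsechase
Title: Source-Sink Carbon Allocation from 13C Pulse-Chase Labeling, Sugar
    Assay Calibration, and Trait-Expression Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stable-isotope 13C pulse-chase experiments
    in woody plants. Converts raw isotope ratios or delta-13C readings into
    atom percent, excess 13C mass, per-organ allocation percentages and
    transport rates via atom-percent-excess mass balance; calibrates
    colorimetric (anthrone) and HPLC sugar assays against standard curves;
    screens sugar contents against enzyme activity panels and gene expression
    against sucrose trajectories with Pearson correlation and significance
    stars; filters differential-expression tables and summarises overlaps; and
    assigns compact-letter displays from one-way ANOVA with Fisher's LSD.
    Includes a seeded synthetic-data generator (first-order source-sink
    compartment model with respiratory loss) so the whole pipeline runs and is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
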