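Package: scfskit
Title: Simulation and Statistics for Single-Cell Force Spectroscopy Adhesion Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for atomic force microscopy (AFM) based single-cell force
    spectroscopy (SCFS) adhesion experiments on integrin-expressing
    fibroblasts. Provides a ground-truth synthetic generator for
    force-distance curves, adhesion-force datasets, single-molecule rupture
    curves and cantilever thermal-noise traces; per-curve feature extraction
    (baseline correction, adhesion force at maximum cantilever deflection,
    rupture-event detection, specific-binding calls, binding probability,
    equipartition spring-constant calibration); and the resampling statistics
    used to compare adhesion kinetics between cell lines: median adhesion
    forces with Mann-Whitney tests, the adhesion-strengthening average-slope
    statistic with an equal-size cell bootstrap and two-tailed Wilcoxon
    testing, and an additive-null interaction statistic between two integrin
    classes with bootstrap Wilcoxon testing. Plain-text curve and dataset
    formats make every step reproducible from a single master seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
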