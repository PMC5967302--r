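Package: myoquant
Title: Quantification of Myotube Morphogenesis, Cortical Actomyosin and
    Membrane Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the quantitative readouts used to study
    phospholipid-flippase- and PIEZO1-dependent myotube formation:
    per-syncytium morphometry (fusion, polarized-elongation and
    differentiation indices from label masks and nuclei centroids),
    cortex-versus-cytoplasm enrichment scoring of peripheral actomyosin
    signal, optical-trap mechanics (equipartition stiffness calibration
    from bead position fluctuations and tether force-extension analysis
    with first-linear-region fitting), and scalar statistics on signal
    traces (Fura2 delta-ratio, relative peak currents, median-intensity
    time courses, positive fractions, 2^-ddCt fold changes). Ships
    synthetic-data generators with known ground truth - Ornstein-Uhlenbeck
    trapped-bead trajectories, series-spring tether pulls, multinucleated
    cell fields, cortical-ring images, agonist-response traces and bimodal
    intensity populations - so every analysis stage is testable without
    microscope, trap or cytometer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
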