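Package: granlif
Title: Rule-Based Reconstruction and Leaky Integrate-and-Fire Simulation of the
    Cerebellar Granular Layer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds three-dimensional models of the cerebellar granular layer
    (granule cells, Golgi cells, glomeruli and mossy fibers) from anatomical
    convergence and divergence rules, and simulates their activity with
    conductance-based leaky integrate-and-fire neurons. Provides Poisson
    background and burst mossy-fiber stimulation protocols, a clock-driven
    engine with per-receptor spike queues and propagation delays, a
    partitioned update mode that reproduces the monolithic simulation
    exactly, closed-form single-cell oracles for validation, a memory
    footprint model, and plain-text readers and writers for networks,
    rasters and membrane traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
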