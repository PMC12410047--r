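Package: voltcon
Title: Mapping Unitary Synaptic Connections from Voltage-Imaging Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for estimating monosynaptic connectivity
    between individual neurons from 1 kHz fluorescence voltage-imaging
    movies of spontaneously spiking cells. Detects optical action
    potentials, builds spike-triggered average videos and subthreshold
    pair averages normalised to each cell's action-potential peak,
    verifies unitary EPSPs with a constrained shifting-window fit, and
    summarises the resulting partially observed directed network
    (connectivity rates, Fisher comparisons, motif census with a
    skeleton-preserving bootstrap null, power-law degree analysis, hub
    detection, and firing-property cell classes). Includes a synthetic
    movie and trace generator that plants known spikes and connections
    so every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
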