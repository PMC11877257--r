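Package: l1ephys
Title: Intrinsic Electrophysiology, Clustering and Connectivity of Cortical
    Layer 1 Interneurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing whole-cell current-clamp recordings of
    cortical Layer 1 interneurons. Extracts twelve intrinsic membrane and
    spike properties from voltage sweeps, classifies late-spiking versus
    non-late-spiking firing patterns, runs an exhaustive feature-subset
    Ward-clustering screen against morphological labels with permutation
    validation, quantifies electrical (gap-junction) and chemical
    (GABAergic) connectivity from paired recordings, and measures
    optogenetically evoked inhibitory currents and spike fidelity. A
    synthetic-data module simulates conductance-based sweeps, labelled
    feature tables, connected pairs and opto datasets with known ground
    truth so that every stage of the pipeline can be validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
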