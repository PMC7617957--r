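Package: barrelcircuit
Title: Quantification of Lineage-Dependent Thalamocortical Circuits in Barrel Cortex
Version: 0.1.0
Authors@R: person("Barrel", "Circuit Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for quantifying the relationship
    between cortical-neuron lineage and thalamocortical input in mouse
    somatosensory (barrel) cortex. Provides laminar electrophysiology
    processing (band splitting, MAD multiunit detection, current source
    density and layer assignment, waveform and optotag classification),
    whisker selectivity-index scoring, paired-recording EPSP input-bias
    measurement, barrel-field histology quantification (layer
    straightening, barrel detection, soma position index, dendritic
    overlap, intensity ratios), sensory-evoked LTP scoring, the
    statistical tests used for group comparisons, and a synthetic-data
    generator with known ground truth for every input modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
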