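Package: retinoconn
Title: Cell-Type-Specific Monosynaptic Connectivity Analysis for Retinocollicular Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects monosynaptically connected retinal ganglion cell to superior
    colliculus (RGC-SC) pairs from simultaneously recorded spike trains using
    jitter-corrected cross-correlograms, and quantifies each connection by its
    synaptic efficacy, contribution, transmission latency, and paired-spike
    (short-term facilitation) dynamics. Includes optogenetic-tagging
    classification of inhibitory versus excitatory SC units, axonal versus
    somatic multi-channel waveform classification, spike-triggered-average
    receptive-field mapping with a functional-similarity index for connected
    pairs, unit-level quality control, a plain-text session file format, and a
    synthetic-session generator that plants ground truth for every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
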