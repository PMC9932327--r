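Package: pcseq
Title: Temporal Sequence Discrimination in a Compartmental Purkinje Cell Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A biophysical multi-compartment model of a cerebellar Purkinje
    cell for studying discrimination and learning of temporal input sequences.
    Provides morphology handling (SWC and GENESIS ".p" readers, synthetic
    reduced trees), Hodgkin-Huxley-type channel kinetics driven by a
    declarative JSON parameter file, an explicit cable-equation solver with an
    implicit reference scheme, directional (IN/OUT) pulse-train stimulation
    over dendritic paths, spike-based response classification with the
    discriminated-sequence ratio, calcium-channel time-constant perturbation
    scans, and a trace-based STDP/LTD plasticity rule with climbing-fiber
    pairing and direction-reversal search.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
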