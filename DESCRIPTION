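Package: hcnax
Title: HCN-Channel Control of Axonal Conduction: Models and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Biophysical modelling and electrophysiology analysis of
    hyperpolarization-activated cyclic-nucleotide-gated (HCN) channels in
    central axons. Provides a single-gate Hodgkin-Huxley description of
    HCN2 gating with weighted global fitting and confidence intervals, a
    compartmental cable simulator of the cerebellar mossy-fiber axon with
    separate Na+/K+ current pathways and ATP-budget accounting, in-silico
    measurement protocols (resting potential, input resistance, sag,
    conduction velocity, high-frequency train fidelity), voltage-clamp
    analysis (tail-current activation curves, Boltzmann and Hill fits,
    ramp-based reversal potential, endogenous cAMP estimation),
    compound-action-potential delay analysis, immunogold quantification
    arithmetic, and seeded synthetic-data generators for every input class.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
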