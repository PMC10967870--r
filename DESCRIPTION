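Package: eegstim
Title: Quantifying Cortical EEG Responses to Focal Vibratory and
    Neuromuscular Electrical Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying stimulus-locked
    cortical responses to focal vibratory stimulation (FVS) and
    neuromuscular electrical stimulation (NMES) in multichannel EEG.
    Implements baseline-corrected event-related potentials with P300
    peak extraction on the midline, band-wise relative spectral power,
    event-related spectral perturbation with a baseline-permutation
    significance mask under FDR control, per-channel ERD/ERS summaries
    for topographic mapping, and a statistical battery including
    cluster-based permutation tests over time, channel and
    time-frequency space, mixed and repeated-measures ANOVA, and
    nonparametric tests with effect sizes. A synthetic-data module
    generates the full factorial stroke/control study design and
    stimulus-locked EEG recordings with known ground truth so that
    every stage of the pipeline is testable end to end, including
    BrainVision and EDF+ round trips.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    nortest,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
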