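Package: bfcoupling
Title: Coupling Analyses Between Basal Forebrain Bursting and Frontal Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking phasic population bursting of basal
    forebrain (BF) neurons to the frontal event-related potential (ERP) in an
    auditory oddball task. Implements bursting-neuron classification by
    bursting index, windowed ROC choice probability with a permutation null,
    single-trial spike-count to EEG/LFP amplitude coupling with quintile
    linear-scaling summaries, millisecond-scale spike-EEG cross-correlation
    on concatenated flanked trial windows, laminar LFP layer-profile
    extraction with cosine-similarity and scalar-projection statistics, and
    stimulation-evoked onset latency detection. Ships a generative forward
    model (graded BF bursting ensemble driving a delayed, linearly scaled
    ERP/LFP) that produces complete synthetic sessions so the full pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
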