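Package: valeeg
Title: Emotional Valence Recognition from Prefrontal EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subject-dependent recognition of emotional valence (happy versus
    sad) from two prefrontal EEG channels. A single difference signal
    (Fp1 - Fp2) is decomposed into the classical EEG rhythms with
    third-order Butterworth band-pass filters, summarized per band by the
    Hjorth parameters (activity, mobility, complexity), zero-crossings and
    total spectral power, and classified per subject with leave-one-out
    cross-validated k-nearest-neighbour or RBF support-vector models.
    Includes readers for EDF recordings and per-subject trial archives,
    rating-threshold labelling utilities, band/timeslot/feature analyses,
    and a synthetic affective-EEG cohort generator with a configurable
    planted frontal-asymmetry effect for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    e1071,
    kernlab,
    lhs,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
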