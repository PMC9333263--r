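Package: voicegate
Title: Voice-Category Coding Analysis for Intracerebral Auditory Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stereoelectroencephalography (sEEG)
    recordings of human auditory cortex during vocal/nonvocal sound
    presentation. Transforms raw multichannel voltage into stimulus-locked
    broadband high-gamma activity (HGA) via a Butterworth filter bank and
    Hilbert analytic amplitude, selects auditory-responsive channels by
    FDR-corrected t-tests, quantifies vocal/nonvocal separability with
    cluster-based permutation tests, measures vocal category preference
    with a clipped HGA ratio, decodes vocal category from multichannel
    activity with L1-regularized logistic regression under nested
    cross-validation, and contrasts acoustic versus categorical encoding
    with nested linear models compared by likelihood-ratio tests. A
    synthetic-data generator produces voltage recordings, trial schedules,
    and acoustic feature tables with known ground truth so every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
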