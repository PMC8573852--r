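Package: sightscore
Title: Scoring of Sight-Reading Performances and Eye-Movement Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing recorded musical sight-reading experiments.
    Generates systematic four-bar stimulus melodies from rhythmic phrase
    templates and constrained diatonic pitch walks, reads performances from
    Standard MIDI Files or tabular note-event lists, quantizes performed
    onsets to a metric grid (sixteenth notes by default), scores per-note
    onset and pitch correctness and per-melody accuracy, classifies rhythm
    errors into added, skipped, early and late notes with continuous onset
    and pitch deviations, and applies trial- and data-point-level exclusion
    rules to fixation and saccade event tables, including area-of-interest
    (AOI) assignment with first- and second-pass gaze measures and
    visual-angle geometry. A synthetic-data module simulates performers with
    parameterised error rates and left-to-right gaze scans so the whole
    pipeline can be exercised and validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
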