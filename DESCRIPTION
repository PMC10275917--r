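Package: birdtrill
Title: Vocal Consistency, Song-Type Bouts and Playback Habituation Analysis for Trilled Birdsong
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying motor performance in trilled birdsong and
    for analysing female responses to song playback. Implements spectrogram
    cross-correlation (SPCC) vocal consistency scoring of trill notes,
    segmentation of continuous dawn song into song-type bouts with
    quantification of the within-bout warm-up effect, construction of
    dual-song-type playback stimuli with alternating song and silence
    sections, and binomial mixed-model analysis of habituation and
    dishabituation in female vocal responses, including AICc-based
    multimodel inference. A synthetic-song generator with known ground
    truth makes every pipeline stage testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
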