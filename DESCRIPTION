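Package: erpmicro
Title: Trial-by-Trial Topographic Microstate Analysis of ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for trial-by-trial topographic analysis of event-related
    potentials (ERPs) in overt picture naming and similar paradigms.
    Implements reference-free topographic primitives (average reference,
    global field power, spatial correlation), preprocessing of stimulus- and
    response-aligned epochs (zero-phase band-pass filtering, amplitude-based
    artifact rejection, spherical-spline bad-channel interpolation, reaction
    time based trial exclusion, and merging of the two alignments into a
    single encoding-period ERP), topographic atomize-and-agglomerate
    hierarchical clustering (TAAHC) with minimum-duration enforcement and
    Krzanowski-Lai plus cross-validation selection of the number of template
    maps, backfitting of template maps into single trials within fitting
    windows, the topographic consistency randomization test, and crossed
    random-effects regression of per-map durations on psycholinguistic
    predictors (phonological neighborhood density, phonotactic probability,
    name agreement, and related item norms). A synthetic-data generator with
    known ground truth supports end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    lme4,
    lmerTest,
    Matrix,
    MASS,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
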