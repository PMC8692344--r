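Package: somnotype
Title: Sleep EEG Spectral Analysis and Data-Driven Insomnia Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantitative analysis of overnight sleep EEG and
    data-driven discovery of insomnia phenotypes. Computes per-stage
    absolute spectral band power from polysomnographic EEG (5-s epoch FFT
    with automated artifact screening), standard sleep macroarchitecture
    metrics from 30-s hypnograms, the interhemispheric delta-power
    asymmetry index, and the sleep-state misperception index; assembles a
    33-variable per-subject feature matrix and derives subtypes by
    z-scoring, principal component analysis and Ward hierarchical
    clustering with a permutation test for the number of clusters. A
    synthetic polysomnography cohort generator with planted subtype
    structure, hemispheric asymmetry and misperception bias supports
    ground-truth validation of every stage, including an acute
    bedtime-restriction scenario. Reads and writes European Data Format
    (EDF) signals and plain-text hypnogram, arousal and report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
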