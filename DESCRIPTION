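Package: kymotility
Title: Quantification of Single-Molecule Motor Motility from Traced Kymograph Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying the motility of microtubule motor complexes
    from manually traced kymograph tracks, as used in single-molecule TIRF
    assays of bidirectional dynein/kinesin transport. Tracks are segmented
    into runs and pauses against a static-speed threshold, classified as
    static, plus-end directed, minus-end directed or bidirectional, and
    summarized as run lengths, dwell times, average speeds, landing rates and
    processive-event frequencies. Hierarchical (superplot) aggregation from
    single motors through microtubules and movies to experiments is provided,
    together with the nonparametric statistics battery used for such data:
    D'Agostino-Pearson normality gating, Kruskal-Wallis omnibus testing, and
    Conover-Iman or Dunn post hoc comparisons with Holm-Bonferroni
    correction. A stochastic simulator of state-switching bidirectional motor
    tracks (Poisson landing, exponential dwells, detachment, localization
    noise, kymograph rendering) supplies ground-truth datasets for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
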