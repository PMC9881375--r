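Package: nemapep
Title: Targeted Neuropeptidomics and Nictation Analysis for Nematodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative neuropeptidomics of nematode dauer and
    infective juvenile stages. Implements rule-based neuropeptide precursor
    discovery from proteomes (signal peptide plus dibasic cleavage sites,
    with C-terminal amidation and pyroglutamate inference), construction and
    retention-time scheduling of parallel reaction monitoring (PRM) assays
    under concurrency constraints, label-free differential quantification of
    neuropeptides from transition-level reports (transition retention,
    fragment-area aggregation, median MS1 normalization, all-or-nothing
    detection filtering with minimum-value imputation, and log10 t tests),
    simulation-based power analysis over effect-size by sample-size grids,
    detection-overlap statistics, and nictation/locomotion behavioral
    statistics with Dunnett many-to-one comparisons. A synthetic-data module
    generates proteomes, transition reports, and behavioral bout tracks with
    the statistical structure the analysis assumes, so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    mvtnorm,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
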