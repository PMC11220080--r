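Package: rhythmrewrite
Title: Consensus Circadian Rhythmicity Detection and Differential
    Rhythmicity Analysis for Multi-Omics Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative circadian analysis of abundance time
    series across molecular layers (transcripts, whole-cell proteins,
    nuclear proteins). Rhythmicity is called per series by the consensus
    of two independent detectors, a cosinor (harmonic regression) F-test
    and a nonparametric Kendall-tau cosine-template permutation test, with
    Benjamini-Hochberg adjustment for transcript sets. Series are then
    classified between two environmental conditions as losing, gaining or
    retaining rhythmicity, circular phase shifts are quantified, call sets
    are joined across layers at the gene level to partition where
    rhythmicity arises, and population-level summaries (cumulative daily
    abundance change, amplitude comparisons, phase histograms) are
    computed. Includes TMT bridge-channel normalization, detection filters
    for transcript counts, and a synthetic two-condition multi-omics
    generator with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
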