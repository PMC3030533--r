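Package: leafnet
Title: Motif-Based Transcriptional Module Discovery and Regulatory Network
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage reverse engineering of a leaf transcriptional
    regulatory program. Stage one discovers transcriptional modules: sets of
    co-expressed genes whose promoters share an over-represented combination
    of sequence motifs, found by a level-wise search over motif combinations
    with hypergeometric significance and false discovery rate control. Stage
    two infers the regulatory mechanism of each module by least-squares
    regression of the concatenated module expression profile on transcription
    factor expression, including pairwise cross terms whose sign separates
    synergistic from competitive regulation; model order grows under a
    cross-validated test for the difference between two dependent Pearson
    correlations with Bonferroni correction. The package also provides
    bootstrap edge-stability and hold-out prediction analysis,
    leave-one-experiment-out validation, cross-species projection of
    mechanisms through a homolog map with a gene-shuffling conservation null,
    position frequency matrix redundancy reduction, annotation enrichment,
    and a synthetic data generator with planted ground truth for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
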