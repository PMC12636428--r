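Package: adscout
Title: Active Learning for Discovery and Quantification of
    Transcriptional Activation Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-to-activity modeling of transcriptional activation
    domains (ADs) with uncertainty-guided active learning. Provides protein
    tiling and greedy identity clustering of a protein design space, one-hot
    and pluggable protein-language-model encodings, a residual convolutional
    activity regressor trained with Adam and early stopping, deep-ensemble
    epistemic uncertainty, quantile-balanced uncertainty acquisition,
    sort-seq (FACS bin + barcode sequencing) activity scoring, cross-dataset
    harmonization over the assay's linear range, additive per-position
    sequence attributions, and a synthetic activity oracle plus sort-seq
    simulator so the full active-learning loop can be exercised end to end
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
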