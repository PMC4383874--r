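Package: evinet
Title: Evidence Construction for Protein Functional-Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds probabilistic functional-association evidence from
    microarray co-expression data: inclusion filtering of experiments and
    samples, per-channel normalization, probe-to-gene merging, Hobohm-2
    redundancy pruning of arrays, gene-by-gene correlation, calibration of
    raw correlations against pathway co-membership gold standards, and
    noisy-OR combination of evidence channels. Also provides hierarchical
    orthologous-group self-consistency repair with interolog transfer of
    scored interactions across species, annotation-term enrichment
    statistics with false-discovery control, and a synthetic-data
    generator with planted co-regulated modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
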