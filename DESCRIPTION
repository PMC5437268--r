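Package: lbseq
Title: Liquid-Biopsy Sequencing Variant Filtering and Cohort Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analytics for hybrid-capture liquid-biopsy sequencing (LB-Seq) of
    circulating tumour DNA: a tumour LOD (log10 likelihood-ratio) statistic for
    candidate substitutions from read counts, per-sample modified Z-score
    filtering of LOD scores with ROC-trained thresholds, germline
    population-allele-frequency filtering, cohort concordance and specificity
    evaluation against bone-marrow truth sets, binomial plasma input-mass and
    library-complexity models, and a synthetic call-table generator for
    end-to-end testing without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
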