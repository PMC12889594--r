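Package: plaqueomics
Title: Differential Abundance, Co-Expression Networks and Consensus Ranking for Paired Plaque Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of paired plaque versus non-plaque
    protein-group intensity matrices from laser-capture
    microdissection DIA proteomics. Implements detection-aware
    differential abundance (G-test gated minimum-value imputation,
    empirical-Bayes moderated paired t-tests, log2 fold-change
    z-scores), temporal trajectory classification across ages,
    permutation-screened planar filtered co-expression networks with
    module, hub and module-trait statistics, order-statistics
    consensus ranking across independent studies, and Fisher
    overrepresentation analysis, together with a synthetic-cohort
    generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    fgsea,
    mclust,
    optparse
Config/testthat/edition: 3
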