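Package: confects
Title: Confident Effect Sizes for Differential Expression Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Ranks genes by confident effect size ("confect"): per-gene lower
    confidence bounds on the magnitude of log2 fold change, obtained by
    inverting the TREAT fold-change threshold test through nested
    Benjamini-Hochberg selections so that the bounds hold simultaneously at a
    chosen false discovery rate and provide false coverage-statement rate
    control for any top slice of the ranking. Includes moderated two-group
    statistics via empirical Bayes variance shrinkage, six competing ranking
    strategies for benchmarking, and a heteroscedastic RNA-seq simulation
    harness that measures top-k ranking accuracy and achieved FDR/FCR.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
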