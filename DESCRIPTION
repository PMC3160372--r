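Package: rcrnet
Title: Reverse Causal Reasoning on Signed Causal Transcriptional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and interrogates typed, signed causal knowledge graphs of
    the kind used to model lung cell proliferation biology. Implements the
    State-Change differential-expression filter chain for two-group microarray
    contrasts (quantile normalization, RMA-style summarization, moderated
    t-statistics, Benjamini-Hochberg correction, fold-change and abundance
    gates), a Reverse Causal Reasoning engine that scores candidate upstream
    controllers with hypergeometric richness and binomial concordance
    p-values, a network verification workflow (consistency matrices, coverage
    statistics, expansion-candidate listing), and a synthetic benchmark
    generator that plants active controllers so the whole pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    limma
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
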