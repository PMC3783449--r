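Package: dlatools
Title: Differential Language Analysis of Social-Media Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Open-vocabulary differential language analysis for
    person-level outcomes. Extracts words, phrases (1-3-grams passing a
    pointwise-mutual-information collocation filter), LDA topic usage and
    closed-vocabulary (LIWC-style) category features from message corpora;
    relates every feature to demographic and psychometric outcomes by
    mass-univariate covariate-adjusted least squares with Bonferroni or
    Benjamini-Hochberg control; renders correlation-scaled word clouds and
    covariate-adjusted LOESS age trends; and compares open- versus
    closed-vocabulary feature sets in an out-of-sample predictive
    evaluation. Includes a synthetic-corpus generator with planted
    language-outcome effects for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'cli.R'
    'corpus-io.R'
    'dla.R'
    'lda.R'
    'lexica.R'
    'ngrams.R'
    'predict.R'
    'synth.R'
    'tokenize.R'
    'viz.R'
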