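Package: pacenet
Title: Progression Pace Subtyping and Network Medicine for Parkinson's
    Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for longitudinal disease-progression
    analysis in Parkinson's disease. Learns per-participant progression
    embeddings from multivariate clinical time series with a recurrent
    (LSTM) sequence autoencoder, discovers progression-pace subtypes by
    Ward hierarchical clustering with multi-index cluster-number voting,
    characterises subtypes with linear mixed-effect progression rates and
    biomarker comparisons, grows subtype molecular modules on a
    protein-protein interactome (random-walk score smoothing,
    hypergeometric connectivity, greedy module growth), screens drugs for
    signature reversal with a Kolmogorov-Smirnov style enrichment score
    and permutation significance, and estimates real-world treatment
    effects by target-trial emulation with propensity-score matching and
    Cox models. Ships a synthetic-data module that generates every input
    with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    lme4,
    survival,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    mclust,
    pROC,
    cluster,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'classifier.R'
    'dppe.R'
    'emulation.R'
    'io.R'
    'network.R'
    'pacenet-package.R'
    'preprocess.R'
    'stats.R'
    'repurpose.R'
    'subtype.R'
    'synthetic.R'
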