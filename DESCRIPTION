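Package: metaboDecomp
Title: Efficacy/Bias Decomposition of Pharmacometabolomic Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes a drug's metabolomic footprint in a four-group
    (control / challenge / challenge+drug / drug-alone) design into
    efficacy-related responses (metabolites the drug restores toward
    baseline) and drug-bias responses (drug-intrinsic shifts outside the
    control-challenge interval). Provides NIPALS partial least
    squares-discriminant analysis with VIP scoring, per-metabolite
    differential testing with Benjamini-Hochberg correction, the
    efficacy/bias classification rule, hypergeometric metabolite-set
    over-representation analysis, centrality-weighted pathway enrichment
    with a permutation null, and a dual-axis (logP vs foldP) pathway
    ranking. A synthetic cohort generator with full ground truth supports
    calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'synthetic.R'
    'preprocess.R'
    'plsda.R'
    'classify.R'
    'enrichment.R'
    'dualaxis.R'
    'pipeline.R'
    'metaboDecomp-package.R'
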