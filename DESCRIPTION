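Package: typostab
Title: Estimating and Comparing the Evolutionary Stability of Typological Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seven published estimators of the evolutionary stability of discrete
    structural (typological) features of language, re-implemented as one tested
    pipeline: Mantel, coherence and rank consistency with the overall typological
    distance pattern; Maslova's transition-probability method on pairs of related
    languages; Wichmann and Holman's metric C contrasting within- and cross-family
    value sharing; Parkvall's family/area homogeneity ratio (all families and an
    accepted-families variant); and a simplified phylogenetic rate-of-change
    estimator (Mk maximum likelihood and parsimony on classification-derived
    trees). Includes the cross-method comparison stage (relative ranks, pairwise
    correlations, outlier flagging, method distances with classical MDS and a
    random-point null, principal components agreement, per-feature interquartile
    disagreement with a permutation null and Holm correction, and an area ANOVA),
    a packaged features-by-methods relative-rank matrix for 142 WALS features,
    and a synthetic-world generator with known per-feature change and borrowing
    rates for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
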