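Package: uEVstrat
Title: Stratification of Subjects from Urinary Extracellular-Vesicle
    Spectral-Count Proteomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A label-free spectral-count (SpC) proteomics pipeline for
    stratifying subjects from urinary extracellular-vesicle protein
    profiles and linking the resulting proteome groups to respiratory
    impedance phenotypes. Run-level protein lists are aligned into a
    proteins-by-runs count matrix, total-count normalized, quality
    controlled across technical replicates, detection-frequency filtered
    and replicate-averaged (aSpC). Subjects are stratified by Ward
    hierarchical clustering; discriminant proteins are screened by
    per-protein one-way ANOVA F ratio and modeled by linear discriminant
    analysis with a shrinkage-regularized common covariance and
    Mahalanobis assignment; differential expression is scored by the
    DAve and DCI spectral-count indices; compact marker panels type
    subjects through per-subject alpha-value profiles; and proteome
    groups are compared on forced-oscillation-technique impedance
    Z-scores by Kruskal-Wallis tests with Dunn-Holm post hoc
    comparisons. A seeded negative-binomial simulator generates
    cohort-scale synthetic data with planted group structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
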