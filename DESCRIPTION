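Package: anfisFS
Title: Neuro-Fuzzy Classification of Gene Expression with Metaheuristic
    Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Wrapper feature selection and neuro-fuzzy classification for
    high-dimensional gene-expression matrices (genes >> samples, binary
    phenotype).  Gene subsets are searched with a grey wolf optimizer
    refined by adaptive beta-hill climbing; classification uses a
    first-order Sugeno adaptive neuro-fuzzy inference system (ANFIS) with
    generalized bell membership functions, whose premise parameters are
    tuned by a chimp-style population metaheuristic with least-squares
    consequent estimation.  Includes z-score preprocessing, a seeded
    synthetic microarray generator, stratified cross-validation and
    holdout protocols, and per-class/macro metrics (accuracy, recall,
    specificity, precision, F-score, G-measure).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    class,
    MASS,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
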