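Package: epiprs
Title: Polygenic Risk Analysis of Severe, Presumed Monogenic Epilepsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying the polygenic
    background of severe epilepsies such as the developmental and epileptic
    encephalopathies. Generates case/control cohorts and affected-proband
    trios under a liability-threshold model combining a polygenic component
    with a rare dominant variant of major effect, and implements the full
    analysis chain: genotype quality control (call rate, minor allele
    frequency, Hardy-Weinberg exact test, LD pruning, relationship-matrix
    PCA), polygenic risk scoring by p-value thresholding with allele
    harmonisation, covariate-adjusted logistic association with Nagelkerke
    pseudo-R2, inverse-variance fixed- and random-effects meta-analysis with
    heterogeneity statistics, the polygenic transmission disequilibrium test
    in trios, and a rule-based rare-variant qualifying screen that stratifies
    cases into screen-positive and screen-negative groups.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
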