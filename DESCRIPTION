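Package: metalip
Title: Local Invasion Power Analysis and Early Metastasis Risk Modeling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the local invasion power (LIP) of germline and
    somatic variants from matched normal, paracancer and tumor tissue
    variant allele fractions; screens candidate metastasis driver and
    resister variants through a three-step cascade (per-variant mean LIP,
    case-control odds ratio, eQTL direction plus Kaplan-Meier/log-rank
    survival penetrance); and fits a LIP-weighted logistic regression
    classifier for early metastatic risk with leave-one-out and
    leave-one-cohort-out evaluation. Includes a fully seeded synthetic
    cohort generator that emulates binomially sampled read depths over
    germline genotypes, tissue purities, planted driver/resister effects,
    odds-ratio enrichment, eQTL slopes and survival hazard differences,
    so the whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
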