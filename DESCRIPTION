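Package: osimc
Title: Quantification of the Osteosarcoma Tumor Microenvironment from Imaging Mass Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for tissue-microarray imaging mass cytometry
    of osteosarcoma biopsies. Provides core- and marker-level quality control,
    rule-based single-cell phenotyping from binary marker calls, per-core
    abundance and composite immunosuppressive-cell (IMSC) scores, M2-macrophage
    centric spatial proximity and density statistics within a configurable
    radius, median-dichotomized Kaplan-Meier / log-rank / Cox survival
    stratification, a co-culture cytokine differential-abundance screen
    (two-way ANOVA with Tukey post hoc and a two-of-three cell-line rule),
    and a marked-point-process synthetic cohort generator for testing every
    stage without access to the original tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
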