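Package: mirtriprong
Title: Tri-Pronged Identification of MicroRNA Targets During Adipogenic
    Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for nominating microRNA gene targets
    from stem-cell differentiation experiments, modelled on the miR-320
    family / RUNX2 axis in human mesenchymal stem cells. Covers two-channel
    miRNA array Lowess normalization with one-way ANOVA, Tukey HSD and
    Bonferroni time-course differential expression; percentile-shift
    normalization and fold-change/t-test screens for one-channel expression
    matrices; canonical seed-match (8mer, 7mer-m8, 7mer-A1) target
    prediction with family grouping and inverse-correlation ranking;
    three-way evidence intersection with hypergeometric gene-set
    enrichment; and quantification math for the validation assays
    (overlap-extension primer assembly, delta-delta-Ct qPCR, dual
    luciferase, plate readers). A synthetic-data generator with planted
    ground truth makes every stage testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    Biostrings,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
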