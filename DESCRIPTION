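Package: CTscreen
Title: Cancer/Testis Gene Screening from Multi-Tissue Expression Matrices
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens log2 expression matrices spanning testis/germ-cell
    compartments, normal somatic tissues and cancer subtypes for cancer/testis
    (CT) gene candidates. Implements global expression thresholding (background
    expression cutoff and quartile confidence tiers), tissue-specificity
    classification (SET, SEHET, PET, PEHET, IE, UE), cancer-upregulation
    classification (UC, UHEC, UCNDH, UHECNDH) with an empirical-Bayes moderated
    t-statistic and Benjamini-Hochberg false discovery rate control, and
    intersection of the two screens into CT-candidate and core-CT calls with
    probeset-to-gene collapsing. Ships a planted-truth simulator that emulates
    the multi-tissue compendium structure so the whole pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse,
    jsonlite
biocViews: GeneExpression, Microarray, DifferentialExpression, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
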