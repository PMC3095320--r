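Package: promoterglow
Title: Promoter Strength Quantification from Reporter Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies plant promoter strength from green fluorescent
    protein (GFP) reporter assays and places promoter gene families in a
    phylogenetic context. Implements transient-expression time-course
    quantification normalized to a CaMV35S reference, hairy-root image
    intensity scoring with local background and negative-control
    correction, one-way ANOVA with Tukey HSD compact letter displays and
    Low/Moderate/High strength classification, transgene copy-number
    regression, and Poisson-corrected neighbor-joining trees with
    bootstrap consensus supports. Ships a synthetic-data generator with
    known ground truth so the whole pipeline is testable without raw
    images or genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    seqinr,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
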