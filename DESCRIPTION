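Package: svrhcc
Title: Genomic Characterization of Hepatocellular Carcinoma After HCV Cure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for the tumor/normal genomic analysis
    of hepatocellular carcinomas arising after hepatitis C virus clearance.
    Implements ten-criterion somatic-variant filtering with a per-criterion
    audit trail, a cancer-gene catalogue with driver annotation and tumor
    mutation burden, 96-context mutational-signature decomposition against a
    reference signature matrix, copy-number gain/loss/copy-neutral-LOH
    classification with integrative expression-by-copy-number driver
    aberration calling, gene-set expression signature scoring (including a
    four-gene TP53-inactivation score), cohort contingency and survival
    statistics, and a seeded synthetic-cohort generator that emulates the
    statistical structure of such a study for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
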