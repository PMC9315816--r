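Package: cnvCircuits
Title: From Copy Number Variants to Developmental Brain Circuits and Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A multi-stage inference pipeline linking pathogenic copy number
    variants (CNVs) in autism cohorts to behavioral phenotypes through
    molecular and neuroanatomical evidence. CNV intervals are mapped to
    spanned genes, combined with a neurodevelopmental gene list, and tested
    for pathway over-representation with a hypergeometric test. Surviving
    genes are filtered by high-confidence protein-protein interactions and
    by mRNA co-expression, assigned a site of maximal developmental brain
    expression (brain region by trimester epoch), mapped onto Research
    Domain Criteria (RDoC) neural circuits, and the behavioral scores of
    circuit-variant carriers are contrasted against subjects with normal
    microarrays. A seeded synthetic-study generator with planted pathway,
    interaction, co-expression, expression-peak and behavioral structure
    makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
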