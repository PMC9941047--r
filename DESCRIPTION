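Package: ptmb
Title: Persistent Tumor Mutation Burden from Allele-Specific Copy Number
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates per-mutation multiplicity and cancer cell fraction
    from somatic mutation read counts, tumor purity and allele-specific
    segmental copy number, classifies mutations as multi-copy, only-copy
    (persistent) or loss-prone, and derives sample- and cohort-level
    metrics: persistent tumor mutation burden (pTMB), aneuploidy and
    whole-genome doubling calls, background rates of genomic loss in
    diploid versus haploid chromosome arms, TMB/pTMB reclassification
    curves, response-association statistics, and longitudinal tracking of
    mutation loss in serial tumor samples. Includes a synthetic tumor
    genome simulator with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    IRanges,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
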