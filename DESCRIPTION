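Package: FamVarPrio
Title: Family-Based Exome Variant Prioritization and Gene-Set
    Overrepresentation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate disease variants from exome sequencing
    of multiplex families. Implements a per-family filter cascade
    (consequence whitelist, artifact blacklist, population-frequency
    cutoff, in-silico damaging predictions, shared-by-all-sequenced-
    members rule), cross-family gene-sharing aggregation with an
    identical-variant flag, gene-set overrepresentation statistics
    (log-space hypergeometric right tail and the conservative EASE
    variant) against a configurable background universe, pedigree
    co-segregation classification, and a fully seeded synthetic-cohort
    generator (pedigrees, Mendelian genotype transmission, annotated
    variants, term sets) with planted truths for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, VariantAnnotation, Pathways, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'FamVarPrio-package.R'
    'aggregate.R'
    'cohort-io.R'
    'enrich.R'
    'filter.R'
    'methods.R'
    'pipeline.R'
    'segregation.R'
    'simulate.R'
    'utils.R'
    'variants-io.R'
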