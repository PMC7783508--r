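Package: cnvtier
Title: Five-Tier Pathogenicity Classification of Microarray CNV Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretation workflow for copy number variants (CNVs) detected by
    chromosomal microarray in clinical cohorts. Applies per-platform sample
    quality-control gates (MAPD, SNPQC, waviness SD) and per-call inclusion
    filters (probe coverage, type-specific size minima, autosomes only,
    known-causative-locus exclusion), gathers evidence by reciprocal
    genomic-interval overlap against benign-population, affected-patient,
    gene (OMIM-flagged) and syndrome-region reference tracks, assigns one of
    the five ACMG-style pathogenicity tiers (benign, likely benign, VUS,
    likely pathogenic, pathogenic) through an ordered rule engine with an
    auditable reason trail, reclassifies recurrent cohort variants at or above
    a 2% carrier frequency as benign, and produces cross-tabulated cohort
    summaries. Includes a seeded synthetic-cohort generator with ground-truth
    labels so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
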