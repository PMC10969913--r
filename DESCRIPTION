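Package: sexvar
Title: Sex-Exclusive Variant Discovery in Small Matched Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of sex-exclusive (perfect-split) variants in small
    matched whole-exome sequencing cohorts. Reads per-patient VCF call sets,
    builds a variant-by-patient presence matrix, applies an exact two-sided
    Fisher test for sex-exclusive presence patterns (for a 4-vs-4 design the
    perfect split attains p = 2/70 = 0.0286), summarizes variant types by
    genomic region class, aggregates significant variants per gene, and
    normalizes immunoblot densitometry for follow-up protein validation.
    Includes a seeded synthetic-cohort simulator with planted sex-exclusive
    variants and bundled reference tables of female- and male-exclusive
    variants from an eight-patient steatohepatitis cohort study for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    withr
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
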