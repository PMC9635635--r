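Package: crossqc
Title: Curation of SNP Genotypes from Two-Generation Experimental Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control and curation of raw SNP allele calls from
    two-generation experimental crosses (F2 intercrosses and N2 backcrosses)
    genotyped on Illumina-style arrays such as the Mouse Universal Genotyping
    Arrays (MUGA). Reads long-format allele-call files, builds a per-marker
    ledger of parental alleles, genotype counts and filter flags, and applies
    a cascade of filters: marker-set matching between parents and offspring,
    parent/offspring allele consistency, missingness, polymorphism, Mendelian
    segregation proportions (proportion or chi-square mode), and a
    recombination-fraction map-sanity filter based on pairwise EM estimation
    of adjacent-marker recombination fractions with Haldane distances.
    Exports curated genotypes as an R/qtl "csv" cross file and a marker
    report. Includes a cross simulator with injectable error classes for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    stats,
    utils,
    optparse,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
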