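Package: beemethyl
Title: Gene Body Methylation Dynamics in Honey Bee Bisulfite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing gene body CG methylation dynamics across
    developmental stages from whole-genome bisulfite sequencing count
    tables. Implements weighted methylation aggregation at site, exon and
    gene resolution, differential methylation calling with Fisher exact
    tests and biological-replicate concordance, the signed
    percent-methylation-change statistic with partial/full classification,
    gene-aligned metaprofiles, single-read epiallele classification,
    expression and splicing integration (gene responsiveness, set-overlap
    representation factors, differential percent-spliced-in calling), and
    non-CG (CA/CT) context analysis. Includes a seeded synthetic methylome
    generator with a ground-truth ledger for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
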