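Package: supermatrixr
Title: Taxonomy-Aware Assembly of Phylogenetic Supermatrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating sequence-repository data into partitioned
    phylogenetic supermatrices. Covers fuzzy resolution of scientific names
    against a Darwin Core reference taxonomy, admissibility filtering and
    tiering of sequence records, baited extraction of target loci against
    per-genus reference databases, rogue-accession detection from all-by-all
    similarity hits, monophyly-aware selection of one representative per
    species, gap-threshold alignment trimming and concatenation with
    partition accounting, and compilation of fossil calibrations into
    penalized-likelihood dating configurations. A deterministic synthetic
    data generator with planted ground truth makes every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    tibble,
    purrr,
    stringr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
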