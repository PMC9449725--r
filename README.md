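# supermatrixr

Taxonomy-aware assembly of phylogenetic supermatrices from
sequence-repository data.

## The problem

Building a species-level phylogeny from public sequence repositories is
mostly not a tree-inference problem — it is a curation problem. Names
attached to sequences follow repository taxonomy, not the current
classification, and include synonyms, spelling errors, and authorship
variants. Accessions may be misidentified or contaminated ("rogues").
Several accessions per species must be reduced to one representative per
locus without concatenating sequences that belong to different organisms.
Loci must be aligned, trimmed, and concatenated into a partitioned
supermatrix, and fossil calibrations must be bound to tree nodes for
divergence-time estimation.

`supermatrixr` implements these curation stages as composable, tested R
functions, developed around plastid supermatrices for ferns (7 classic
Sanger loci — *atpA*, *atpB*, *matK*, *rbcL*, *rps4*, *trnL*–*trnF*,
*rps4*–*trnS* — plus a 79-locus plastome set) but applicable to any
single-copy marker system. External aligners, tree builders and dating
tools (MAFFT, FastTree/IQ-TREE, treePL) are *not* re-implemented: the
package prepares their inputs and consumes their outputs.

## What it does

- **Name resolution** against a Darwin Core reference taxonomy:
  author-format-tolerant parsing (parenthetical basionym authors),
  exact → canonical → fuzzy (Levenshtein) matching with explicit
  ambiguity reporting, one-hop synonym resolution, and structural
  validation of the taxonomy itself (`match_name`, `validate_taxonomy`).
- **Harvest**: admissibility filtering (environmental samples, `aff.` /
  `cf.` annotations, hybrid formulas are excluded), Sanger vs plastome
  tiering at the 7,000 bp accession-length cutoff, per-genus longest
  reference databases, and baited extraction of target loci by local
  alignment (`extract_locus`).
- **Rogue detection**: an accession whose top three distinct all-by-all
  similarity neighbours all belong to a different family is flagged;
  Cyatheales compare at order level and Saccolomatineae at suborder level
  (closely related small families), and monotypic families are exempt
  (`detect_rogues`).
- **Representative selection**: species are classified monophyletic if
  their accessions form a clade in every gene tree containing at least
  two of them; accessions concatenate under any of three conditions
  (species monophyly, shared voucher, single publication); the final set
  per species maximizes rbcL presence, then total ungapped length
  (`select_sanger_representative`); plastome specimens are chosen by
  greatest combined length (`select_plastome_representative`).
- **Supermatrix assembly**: gap-threshold column trimming (a column is
  removed when its gap fraction strictly exceeds the threshold; 5% for
  coding loci, 1% for spacers by default), family-level subalignment
  planning for spacers (minimum group size 3, merge-table emission), and
  concatenation with partition ranges and missing-data accounting
  (`trim_gappy_columns`, `concatenate_supermatrix`).
- **Calibration compilation**: root-on-outgroup-and-trim, MRCA binding
  of crown/stem fossil constraints, redundant-fossil resolution by
  oldest minimum age, and emission of penalized-likelihood (treePL
  dialect) configurations with a fixed land-plant root at 475 Ma, a stem
  euphyllophyte minimum of 407.6 Ma, and a smoothing sweep over
  1e-12 … 1e-06 (`assign_calibration_nodes`, `write_treepl_config`).
- **Synthetic fixtures**: `make_toy_dataset()` generates a complete
  offline input bundle — taxonomy with planted synonyms and
  misspellings, simulated sequences, planted rogues, gene trees, fossil
  calibrations — together with a manifest of expected outputs, so the
  whole pipeline is testable without network access.

## Worked example

```r
library(supermatrixr)

b <- make_toy_dataset(seed = 42, n_families = 4, n_species_per_family = 4,
                      n_loci = 2, rogue_rate = 0.1)
b
#> <fixture_bundle> seed 42: 18 species, 37 Sanger records, 769 hits,
#>   2 gene trees, 1 planted rogues

rep <- detect_rogues(b$hits, b$manifest$expected_resolution, b$taxonomy)
table(rep$status)
#>            clean exempt_monotypic            rogue
#>               35                1                1
rep$accession[rep$flagged]
#> [1] "A0404rbcL1"
```

The one flagged accession is exactly the planted rogue: its sequence was
copied from another family, so its three nearest neighbours all disagree
with its label. The monotypic-family sequence has foreign neighbours too
but is exempt from the rule. Selection then reduces the surviving
records to one representative per species:

```r
mono <- classify_species_monophyly(b$gene_trees,
                                   b$manifest$expected_resolution)
keep <- b$records[!b$records$accession %in% rep$accession[rep$flagged], ]
sel <- select_sanger_representative(build_concat_groups(keep, mono))
table(sel$rule)
#> S1 S2 S3
#> 10  6  1
```

Ten species have an rbcL-plus-another-locus concatenation (rule S1), six
are represented by their longest rbcL alone (S2), and one species — which
lost its only rbcL to the rogue filter — falls through to the longest
remaining accession (S3).

`run_pipeline(b)` chains all stages (resolution, filtering, rogues,
selection, supermatrix, calibrations) and returns every intermediate. A
thin command-line wrapper with subcommands (`make-fixtures`,
`resolve-names`, `filter-rogues`, `check-monophyly`,
`build-supermatrix`, `compile-calibrations`) is installed at
`inst/scripts/supermatrixr-cli.R`; each run writes a machine-readable
`run-log.json`.

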