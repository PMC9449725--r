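---
title: "Curation methods: from repository sequences to a dated supermatrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation methods: from repository sequences to a dated supermatrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supermatrixr)
```

This vignette documents the models and decision rules the package
implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable implementation existed.

## Name resolution

Repository organism names are parsed into a canonical part (genus +
epithets) and an authorship string. Authorship is deliberately excluded
from the primary match key because author formatting varies widely —
most importantly, the parenthetical basionym author may be present or
absent ("(Wall. ex Hook.) Copel." vs "Copel.") without any taxonomic
difference. Matching proceeds in three stages:

1. exact canonical + authorship;
2. exact canonical;
3. fuzzy canonical by Levenshtein distance.

The fuzzy budget defaults to one edit per 10 characters of the
canonical name, capped at 3. This scales tolerance with name length (a
single typo in a 20-character binomial is common; three edits in an
8-character name would usually be a different name). Candidates at equal
canonical distance are ranked by similarity of *normalized* authorship
(case, punctuation and parentheses stripped), so authors break ties but
can never block a match. Remaining ties are returned as `ambiguous` and
are never auto-resolved: in curation practice, ambiguous matches are
exactly the cases requiring human inspection. Names with an
infraspecific epithet only compare against other trinomials; allowing a
trinomial to fuzzily collapse onto a binomial would create
rank-collapsing false positives at small distances.

Synonym resolution is a single pointer hop. This is safe because
`validate_taxonomy()` enforces the Darwin Core invariants first: unique
identifiers, no synonym-to-synonym chains, no dangling pointers, acyclic
parent links. Taxonomy edits go through `edit_taxonomy()`, which applies
rows transactionally and re-validates, rejecting any edit that would
break the invariants.

## Admissibility and tiering

Records are excluded when the name carries `aff.` or `cf.` (open
nomenclature: the sequencer themself was unsure of the identification),
marks an environmental/uncultured sample, or is a hybrid formula (two
binomials joined by a multiplication sign). Hybrid taxa with standard,
non-formula names are kept. Every exclusion carries a reason code.

Repositories have no formal flag separating PCR/Sanger records from
whole-plastome assemblies, so tiering uses an empirical cutoff on total
accession length: ≤ 7,000 bp is Sanger, > 7,000 bp plastome. The
boundary is honored verbatim (7,000 → Sanger, 7,001 → plastome).

## Baited extraction

Target loci are pulled out of candidate sequences by local alignment
against per-genus reference ("bait") databases — the longest record per
genus per locus, ties broken by lexicographic accession so rebuilds are
deterministic. The built-in aligner is plain Smith–Waterman with match
+1, mismatch −1, gap −2 (linear), evaluated on both strands; the best
hit is accepted when score ≥ 50 and identity ≥ 0.7. These thresholds are
package defaults chosen so that a ~50 bp exact match (or a longer,
diverged one) counts as significant while unrelated sequence does not;
they are exposed in `extraction_params()`. The extracted span is always
a contiguous substring of the candidate, reverse-complemented onto the
plus strand when needed. A precomputed tabular hit file (BLAST outfmt-6
dialect, 1-based inclusive coordinates) can substitute for the built-in
aligner; both paths extract identical spans for identical hits.
Internally all coordinates are 0-based half-open; 1-based inclusive
appears only in the tabular interchange files.

## Rogue detection

The rogue rule asks whether an accession's nearest neighbours agree
with its label: rank all-by-all hits by (score desc, e-value asc,
subject id asc), collapse multiple rows per subject to the subject's
best row, take the top three *distinct subject accessions*, and flag the
query only if all three belong to a different taxon at the comparison
rank. Three design choices deserve comment:

- **Subjects, not rows.** A single close relative can contribute many
  alignment rows; counting rows would let one neighbour dominate the
  evidence. Three distinct subjects is the natural reading of "top three
  best matches".
- **Fewer than three usable hits → `indeterminate`, never flagged.**
  The alternative (flagging on one or two foreign hits) would
  systematically penalize rare, sparsely sampled families.
- **Conspecific hits are retained.** Only exact self-hits (same
  accession) are dropped; another accession of the same species ranking
  first is the strongest possible evidence that the query is fine.

The comparison rank is family by default. Two override groups ship as
data (`default_rank_overrides()`): Cyatheales compares at order rank and
Saccolomatineae at suborder rank, because both contain several closely
related small families whose sequences legitimately interleave.
Monotypic families are exempt entirely — every neighbour of such a
species is foreign by construction, so the rule cannot be informative. A
subject lacking a name at the comparison rank counts as a different
taxon (it demonstrably is not the query's taxon).

## Monophyly

For unrooted gene trees, a set of tips is monophyletic when it forms a
split (one side of some branch); this is evaluated by rooting at an
arbitrary outside tip and testing the clade condition, which is
equivalent. A species is classified monophyletic when its accessions
form a split in *every* gene tree containing at least two of them;
species never having two accessions in one tree are vacuously
monophyletic. `monophyly_report()` applies the same machinery at genus
rank and above on a species tree, reporting intruding taxa and outlier
tips for non-monophyletic groups.

## Concatenation conditions and selection rules

Blind longest-per-locus concatenation can chimerize misidentified
accessions or non-monophyletic species. Accessions are therefore only
concatenated under one of three conditions, each generating *candidate*
groups (the conditions do not short-circuit one another — they are
listed as "any of", so all applicable candidates enter the pool):

1. the species is monophyletic → one group, longest accession per locus;
2. accessions share a voucher specimen → one group per voucher (same
   physical plant, concatenation always safe);
3. all the species' accessions come from one publication → one group.

Condition 3 is read strictly: *all* accessions of the species must share
the publication. Missing voucher or publication fields never satisfy a
condition — absence of metadata is not evidence of identity. Every
accession additionally stands alone as a `single` candidate, so the
candidate pool always covers the species.

Selection then maximizes representation of rbcL, the most densely
sampled fern locus: (S1) among groups with rbcL plus at least one other
locus, greatest total ungapped length; else (S2) among rbcL-containing
candidates, longest rbcL; else (S3) greatest total length. All sequence
lengths exclude missing characters, whose set is exactly
`{"?", "N", "-"}`. Ties break deterministically by (greater total
length, more loci, lexicographic accession tuple). Curated include
lists override the automated rules (reported as rule `curated`), and
curated excludes beat includes, with the conflict logged. Plastome
species bypass all of this: each plastome accession is one specimen, and
the specimen with the greatest combined length wins; such species are
removed from the Sanger pool.

An open question in the rules as stated is whether a voucher group may
merge with condition-1 longest-per-locus choices inside a single
candidate; the package keeps conditions as separate candidates, which is
the conservative reading (each candidate is justified by exactly one
piece of evidence).

## Alignment trimming and the supermatrix

Column trimming removes a column when its gap fraction **strictly
exceeds** the threshold — a column exactly at the threshold stays, the
usual gap-threshold semantics of alignment trimmers. Only `"-"` counts
as a gap for trimming; `N` and `?` are missing data for accounting but
do not trigger removal. Defaults are 5% for coding loci and 1% for
spacers: the sources describing this workflow state both thresholds
without mapping them to locus classes, so the mapping is configuration,
with the stricter value assigned to the more indel-prone spacers.

Spacer regions align poorly across families, so they are aligned per
family and merged by a merge-capable aligner. Families with ≥ 3 sampled
species form subalignment groups; species of smaller families enter as
singletons (two sequences do not define a usable profile). Anemiaceae is
excluded by default (extreme indel load), as are outgroups. The emitted
merge table is the whitespace-separated index format those aligners
consume.

Concatenation takes the union of taxa (lexicographic order), fills
absent blocks with `"?"`, and reports 1-based inclusive partition ranges
(`DNA, locus = start-end` dialect) that are contiguous, non-overlapping
and covering. Missing fractions count cells in `{"?", "N", "-"}`.
Slicing a partition back out reconstructs the input alignment, and the
FASTA + partition writers round-trip byte-stably.

## Fossil calibrations and dating configuration

For penalized-likelihood dating the tree is first rooted on the
designated outgroup and the outgroup tip is then removed — branch length
cannot be objectively divided across the root, so the outgroup's only
job is to orient the tree. Pruning preserves all pairwise path lengths
among retained tips.

Crown calibrations bind to the MRCA of their anchor taxa; stem
calibrations to that MRCA's parent (when only one anchor is sampled,
the stem is the tip's parent edge node). Calibrations that cannot bind
(missing anchors, or a stem whose crown is already the root) are
reported as unassignable, never dropped silently. When several fossils
bind to one node — typical for stems of sister families — the one with
the **oldest** minimum age is kept (younger minima on the same node are
redundant), ties broken by calibration id.

The emitted configuration uses the treePL dialect (`mrca` / `min` /
`max` / `smooth` / `thorough`). All fossil constraints are minimum ages.
The root is fixed (min = max) at 475 Ma, the conventional land-plant
root age, and a stem-euphyllophyte minimum of 407.6 Ma is emitted when
its anchors are present. The smoothing sweep spans the seven decades
1e-12 … 1e-06; smoothing selection itself happens inside the dating
tool, so the package only collects reported chi-squared values per run
and flags the smallest (`collect_smoothing_chisq()`). A validator checks
any dated tree against a configuration's constraints.

## The synthetic-data generator

`make_toy_dataset()` produces a complete input bundle as a pure function
of its seed and size parameters. Defaults — 5 families × 4 species ×
4 loci, rogue rate 0.1 — are sized so that every rule has work to do:
each family exercises all three concatenation conditions across its
four species, one species is planted non-monophyletic, one family is
monotypic, two families form a Cyatheales-style close pair and a third
sits in a Saccolomatineae-style suborder, and roughly one accession in
ten candidates becomes a planted rogue.

Sequences evolve down the species tree under site-independent
substitution with uniform exchange (Jukes–Cantor style), branch lengths
in expected substitutions per site with per-locus rate multipliers;
within-family divergence (~0.02 per branch) is kept well below
between-family divergence (~0.25 stems) so that similarity ranks reflect
taxonomy. Rogues are created by replacing a sequence with a lightly
mutated (d = 0.01) copy from a donor family differing at the query's
comparison rank; donors are distinct (family, species) pairs so that no
clean query can accumulate three near-identical foreign neighbours and
be falsely flagged. There are no indels except gap columns planted in
the spacer alignment for trimmer tests.

The generator emulates the *logical* structure of repository data, not
its texture: no rate heterogeneity among sites, no indels, no alignment
error, no partial or chimeric sequences, and fossil calibrations are
invented and labelled synthetic. Passing the end-to-end tests therefore
demonstrates that the decision rules are implemented exactly as
specified and recover planted truth under clean conditions; it does not
demonstrate robustness to the noise of real repository data.

The manifest of expected outputs is filled by the generator's own
literal transcription of the selection rules and by the planted truth
(rogue set, non-monophyletic species, calibration winners), kept
deliberately separate from the package's implementation so that
end-to-end agreement is a two-route check.

## Problem sizes and numerical notes

The test suite evaluates the selection rules against a literal oracle on
an exhaustive enumeration of species configurations (≤ 3 loci × ≤ 3
accessions × monophyly × voucher × publication × length patterns), the
rogue rule on 200 random hit tables, monophyly against exhaustive split
enumeration on 500 random trees of ≤ 12 tips, extraction on 100 random
flanked candidates of ≤ 2 kb, and the full pipeline on five fixture
seeds; these sizes exercise every branch of the rules while keeping the
suite quick on a laptop. All tie-breaks in the package are total orders
(lexicographic ids as the final key), so every operation is
deterministic and order-invariant; property tests shuffle input rows to
confirm. Floating-point comparisons never enter the decision rules —
lengths, counts and ages are compared exactly.
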