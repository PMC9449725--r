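#' Default comparison-rank overrides for rogue detection
#'
#' Rogue detection compares taxa at family rank by default, but for
#' groups of several closely related small families a coarser rank avoids
#' false positives. The packaged table raises Cyatheales to order-level
#' comparison and Saccolomatineae to suborder-level.
#'
#' @return A tibble with columns `taxon` and `rank`.
#' @export
default_rank_overrides <- function() {
  tibble::tibble(taxon = c("Cyatheales", "Saccolomatineae"),
                 rank = c("order", "suborder"))
}

#' Detect rogue accessions from an all-by-all similarity table
#'
#' An accession is a putative rogue (misidentified, contaminated, or poor
#' quality) when its nearest similarity neighbours all disagree with its
#' own classification. For each query: exact self-hits (same accession)
#' are dropped, remaining hits are ranked by score (descending), then
#' e-value (ascending), then subject id, multiple rows per subject
#' collapse to that subject's best row, and the top three distinct
#' subject accessions are examined. The query is flagged only when all
#' three belong to a different taxon than the query at the comparison
#' rank. Queries in monotypic families are exempt; queries with fewer
#' than three usable hits are indeterminate and never flagged. A subject
#' lacking a name at the comparison rank counts as a different taxon.
#' Hits to
#' other accessions of the same species are retained (conspecific hits
#' are the strongest evidence the query is fine).
#'
#' @param hits A tibble with columns `qseqid`, `sseqid`, `bitscore`,
#'   `evalue` (extra columns ignored).
#' @param acc2species Named character vector mapping accession ->
#'   species taxon_id.
#' @param taxonomy A validated taxonomy tibble.
#' @param overrides Comparison-rank override table
#'   (default [default_rank_overrides()]): queries whose lineage passes
#'   through `taxon` are compared at `rank` instead of family.
#' @return A tibble of class `rogue_report`, one row per query:
#'   `accession`, `species_id`, `comparison_rank`, `query_taxon`,
#'   `top_hit_taxa` (list column, up to 3), `status` (`clean`, `rogue`,
#'   `indeterminate`, `exempt_monotypic`), `flagged`. Unmapped accessions
#'   are excluded and listed in `attr(, "unmapped")`.
#' @export
detect_rogues <- function(hits, acc2species, taxonomy,
                          overrides = default_rank_overrides()) {
  queries <- sort(unique(hits$qseqid))
  unmapped <- queries[!queries %in% names(acc2species)]
  queries <- setdiff(queries, unmapped)

  lin <- lineage_table(unique(acc2species[queries]), taxonomy)
  lin_of <- function(acc) lin[lin$species_id == acc2species[[acc]], ]

  rank_for <- function(l) {
    if (l$order %in% overrides$taxon) {
      return(overrides$rank[overrides$taxon == l$order][1])
    }
    if (!is.na(l$suborder) && l$suborder %in% overrides$taxon) {
      return(overrides$rank[overrides$taxon == l$suborder][1])
    }
    "family"
  }
  taxon_at <- function(l, rank) switch(rank, family = l$family,
                                       order = l$order, suborder = l$suborder)

  rows <- purrr::map(queries, function(q) {
    ql <- lin_of(q)
    rank <- rank_for(ql)
    qt <- taxon_at(ql, rank)
    h <- hits[hits$qseqid == q & hits$sseqid != q, , drop = FALSE]
    # subjects must be mappable to taxa
    h <- h[h$sseqid %in% names(acc2species), , drop = FALSE]
    h <- h[order(-h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
    h <- h[!duplicated(h$sseqid), , drop = FALSE]
    top <- utils::head(h, 3L)
    top_taxa <- vapply(top$sseqid, function(s) {
      sl <- lin[lin$species_id == acc2species[[s]], ]
      if (nrow(sl) == 0L) {
        sl <- lineage_table(acc2species[[s]], taxonomy)
      }
      taxon_at(sl, rank) %||% NA_character_
    }, character(1), USE.NAMES = FALSE)
    status <- if (isTRUE(ql$is_monotypic_family)) {
      "exempt_monotypic"
    } else if (nrow(top) < 3L) {
      "indeterminate"
    } else if (all(is.na(top_taxa) | top_taxa != qt)) {
      "rogue"
    } else {
      "clean"
    }
    tibble::tibble(accession = q, species_id = acc2species[[q]],
                   comparison_rank = rank, query_taxon = qt,
                   top_hit_taxa = list(top_taxa), status = status,
                   flagged = status == "rogue")
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "unmapped") <- unmapped
  class(out) <- c("rogue_report", class(out))
  out
}

# tips descending from an internal node of a rooted phylo
tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_under, tree = tree))
}

# does tip set form a clade in a rooted tree / a split in an unrooted one?
is_mono_set <- function(tree, tips, rooted = ape::is.rooted(tree)) {
  all_tips <- tree$tip.label
  stopifnot(all(tips %in% all_tips))
  if (length(tips) <= 1L) return(TRUE)
  if (length(tips) == length(all_tips)) return(TRUE)
  if (!rooted) {
    # a set forms a split iff it is a clade after rooting at any outside tip
    out_tip <- setdiff(all_tips, tips)[1]
    tree <- ape::root(tree, outgroup = out_tip, resolve.root = TRUE)
  }
  mrca <- ape::getMRCA(tree, tips)
  desc <- tips_under(tree, mrca)
  length(desc) == length(tips)
}

#' Taxon monophyly report for a tree
#'
#' Classifies each taxon at the requested ranks as `monophyletic`
#' (sampled tips form a clade, or a split when the tree is unrooted),
#' `non_monophyletic`, `monotypic` (exactly one sampled tip) or
#' `unsampled`. For rooted trees, intruders (foreign taxa at the same
#' rank occurring inside the taxon's MRCA subtree) and outliers (the
#' taxon's own tips outside its largest pure clade) are reported.
#'
#' @param tree An `ape::phylo`, tips labelled by species taxon_id (or any
#'   label present in `tip2species` names).
#' @param taxonomy A validated taxonomy tibble.
#' @param ranks Ranks to assess, subset of
#'   `c("genus", "family", "suborder", "order")`.
#' @param tip2species Optional named vector mapping tip label ->
#'   species taxon_id; defaults to tips already being taxon_ids.
#' @return A tibble: `rank`, `taxon`, `status`, `n_tips`, `intruders`
#'   (list), `outliers` (list).
#' @export
monophyly_report <- function(tree, taxonomy,
                             ranks = c("genus", "family", "order"),
                             tip2species = NULL) {
  tips <- tree$tip.label
  if (is.null(tip2species)) tip2species <- stats::setNames(tips, tips)
  bad <- tips[!tips %in% names(tip2species) |
                !tip2species[tips] %in% taxonomy$taxon_id]
  if (length(bad) > 0L) {
    stop("tips with unresolvable species: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lin <- lineage_table(unique(tip2species[tips]), taxonomy)
  tipinfo <- tibble::tibble(tip = tips, species_id = unname(tip2species[tips])) |>
    dplyr::left_join(lin, by = "species_id")
  rooted <- ape::is.rooted(tree)

  purrr::map_dfr(ranks, function(rk) {
    taxa <- sort(unique(stats::na.omit(tipinfo[[rk]])))
    purrr::map_dfr(taxa, function(tx) {
      members <- tipinfo$tip[!is.na(tipinfo[[rk]]) & tipinfo[[rk]] == tx]
      if (length(members) == 0L) {
        return(tibble::tibble(rank = rk, taxon = tx, status = "unsampled",
                              n_tips = 0L, intruders = list(character()),
                              outliers = list(character())))
      }
      if (length(members) == 1L) {
        return(tibble::tibble(rank = rk, taxon = tx, status = "monotypic",
                              n_tips = 1L, intruders = list(character()),
                              outliers = list(character())))
      }
      mono <- is_mono_set(tree, members, rooted = rooted)
      intr <- character()
      outl <- character()
      if (!mono && rooted) {
        mrca <- ape::getMRCA(tree, members)
        inside <- tips_under(tree, mrca)
        # intruders are reported as taxa at the assessed rank, outliers
        # as the focal taxon's own tips outside its largest pure clade
        foreign <- setdiff(inside, members)
        intr <- sort(unique(tipinfo[[rk]][tipinfo$tip %in% foreign]))
        outl <- setdiff(members, core_clade_tips(tree, members))
      }
      tibble::tibble(rank = rk, taxon = tx,
                     status = if (mono) "monophyletic" else "non_monophyletic",
                     n_tips = length(members),
                     intruders = list(intr), outliers = list(outl))
    })
  })
}

# largest clade consisting purely of the given tips (the taxon "core")
core_clade_tips <- function(tree, members) {
  n_tip <- length(tree$tip.label)
  nodes <- (n_tip + 1L):(n_tip + tree$Nnode)
  best <- members[1]
  for (nd in nodes) {
    d <- tips_under(tree, nd)
    if (all(d %in% members) && length(d) > length(best)) best <- d
  }
  best
}

#' Apply curated exclude / include lists to sequence records
#'
#' Manual curation overrides the automated pipeline: excluded accessions
#' are removed (reason `curated_rogue`); include-listed accessions are
#' marked `preferred` so that downstream representative selection must
#' choose them for their species when present. Exclusion beats inclusion;
#' ids on both lists are excluded and the conflict is logged.
#'
#' @param records Sequence-record tibble with an `accession` column.
#' @param exclude_list,include_list Character vectors of accession ids.
#' @return The records tibble with a logical `preferred` column; removed
#'   rows in `attr(, "removed")` (with `reason`), conflicts in
#'   `attr(, "conflicts")`, ids not found in `attr(, "not_found")`
#'   (warned about).
#' @export
apply_curated_lists <- function(records, exclude_list = character(),
                                include_list = character()) {
  conflicts <- intersect(exclude_list, include_list)
  include_list <- setdiff(include_list, conflicts)
  not_found <- setdiff(c(exclude_list, include_list), records$accession)
  if (length(not_found) > 0L) {
    warning("curated ids not present in records: ",
            paste(not_found, collapse = ", "), call. = FALSE)
  }
  removed <- records[records$accession %in% exclude_list, , drop = FALSE]
  if (nrow(removed) > 0L) removed$reason <- "curated_rogue"
  out <- records[!records$accession %in% exclude_list, , drop = FALSE]
  out$preferred <- out$accession %in% include_list
  attr(out, "removed") <- removed
  attr(out, "conflicts") <- conflicts
  attr(out, "not_found") <- not_found
  out
}

#' Write a rogue report as TSV
#' @param report Output of [detect_rogues()].
#' @param path Output path.
#' @export
write_rogue_report <- function(report, path) {
  flat <- report
  flat$top_hit_taxa <- vapply(report$top_hit_taxa, paste, character(1),
                              collapse = ";")
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
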