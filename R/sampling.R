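#' Classify species monophyly across gene trees
#'
#' A species is monophyletic when, in every gene tree containing two or
#' more of its accessions, those accessions form a clade (rooted tree) or
#' a split (unrooted tree). A species never represented by two or more
#' accessions in any tree is vacuously monophyletic.
#'
#' @param gene_trees Named list of `ape::phylo` trees (one per locus),
#'   tips labelled by accession.
#' @param acc2species Named character vector mapping accession ->
#'   species id.
#' @return Named logical vector over all species appearing in the trees.
#' @export
classify_species_monophyly <- function(gene_trees, acc2species) {
  all_species <- sort(unique(unname(acc2species[
    unlist(lapply(gene_trees, function(t) t$tip.label))])))
  res <- stats::setNames(rep(TRUE, length(all_species)), all_species)
  for (tree in gene_trees) {
    tips <- tree$tip.label
    if (any(!tips %in% names(acc2species))) {
      stop("gene tree tips without species mapping: ",
           paste(setdiff(tips, names(acc2species)), collapse = ", "),
           call. = FALSE)
    }
    sp <- acc2species[tips]
    for (s in unique(sp)) {
      members <- tips[sp == s]
      if (length(members) >= 2L && !is_mono_set(tree, members)) {
        res[[s]] <- FALSE
      }
    }
  }
  res
}

new_concat_group <- function(species_id, basis, rows) {
  members <- stats::setNames(rows$accession, rows$locus)
  tibble::tibble(
    species_id = species_id,
    basis = basis,
    members = list(members),
    loci = list(sort(rows$locus)),
    n_loci = length(rows$locus),
    total_len = sum(ungapped_length(rows$seq)),
    rbcL_len = sum(ungapped_length(rows$seq[rows$locus == "rbcL"])),
    has_rbcL = "rbcL" %in% rows$locus
  )
}

# per-locus longest record within a set of rows, deterministic tie-break
longest_per_locus <- function(rows) {
  rows$len <- ungapped_length(rows$seq)
  rows |>
    dplyr::group_by(.data$locus) |>
    dplyr::arrange(dplyr::desc(.data$len), .data$accession, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}

#' Build candidate concatenation groups per species
#'
#' Concatenating across accessions is only safe under evidence they
#' represent the same organism or lineage, so candidate groups are formed
#' under any of three conditions: (1) the species is monophyletic across
#' gene trees — one group taking the longest accession per locus;
#' (2) accessions share a voucher specimen — one group per voucher with
#' two or more accessions, longest per locus within the voucher;
#' (3) all of the species' accessions originate from a single
#' publication — one group, longest per locus. Each unconcatenated
#' accession additionally forms a `single` group. Conditions are
#' evaluated independently ("any of"); groups are candidates only, final
#' selection happens in [select_sanger_representative()]. Missing voucher
#' or publication fields never satisfy conditions 2-3.
#'
#' @param records Admissible Sanger-tier records: tibble with
#'   `accession`, `locus`, `species_id`, `seq`, and optional `voucher`,
#'   `publication` (normalized).
#' @param monophyly_map Named logical vector from
#'   [classify_species_monophyly()]; species absent from the map are
#'   treated as monophyletic (vacuous truth).
#' @return A tibble of candidate groups: `species_id`, `basis`
#'   (`monophyly`, `voucher`, `publication`, `single`), `members` (list:
#'   locus -> accession), `loci` (list), `n_loci`, `total_len`,
#'   `rbcL_len`, `has_rbcL`.
#' @export
build_concat_groups <- function(records, monophyly_map = NULL) {
  if (!"voucher" %in% names(records)) records$voucher <- NA_character_
  if (!"publication" %in% names(records)) records$publication <- NA_character_
  out <- list()
  for (sp in sort(unique(records$species_id))) {
    rows <- records[records$species_id == sp, , drop = FALSE]
    mono <- if (is.null(monophyly_map) || !sp %in% names(monophyly_map)) TRUE
            else monophyly_map[[sp]]
    if (mono) {
      out[[length(out) + 1L]] <-
        new_concat_group(sp, "monophyly", longest_per_locus(rows))
    }
    vs <- unique(rows$voucher[!is.na(rows$voucher)])
    for (v in sort(vs)) {
      vrows <- rows[!is.na(rows$voucher) & rows$voucher == v, , drop = FALSE]
      if (nrow(vrows) >= 2L) {
        out[[length(out) + 1L]] <-
          new_concat_group(sp, "voucher", longest_per_locus(vrows))
      }
    }
    pubs <- rows$publication
    if (nrow(rows) >= 2L && !anyNA(pubs) && length(unique(pubs)) == 1L) {
      out[[length(out) + 1L]] <-
        new_concat_group(sp, "publication", longest_per_locus(rows))
    }
    for (i in seq_len(nrow(rows))) {
      out[[length(out) + 1L]] <-
        new_concat_group(sp, "single", rows[i, , drop = FALSE])
    }
  }
  dplyr::bind_rows(out)
}

# deterministic total order on candidate groups: better first
order_groups <- function(groups, key = groups$total_len) {
  acc_key <- vapply(groups$members, function(m)
    paste(sort(unname(m)), collapse = "|"), character(1))
  order(-key, -groups$total_len, -groups$n_loci, acc_key)
}

#' Select one Sanger representative per species
#'
#' Selection maximizes representation of rbcL, the most densely sampled
#' locus: (S1) among candidate groups containing rbcL plus at least one
#' other locus, pick the greatest total ungapped length; otherwise (S2)
#' among candidates containing rbcL, pick the longest rbcL sequence;
#' otherwise (S3) pick the greatest total length overall. A curated
#' preference list overrides the automated rules: when any preferred
#' accession occurs among a species' candidates, selection is restricted
#' to groups containing one and the rule is reported as `curated`. Ties
#' break by (greater total length, more loci, lexicographic accession
#' tuple).
#'
#' @param groups Candidate groups from [build_concat_groups()].
#' @param curated_preferences Character vector of preferred accessions.
#' @return A tibble of class `selection_result`: one row per species with
#'   `species_id`, `rule` (`S1`, `S2`, `S3`, `curated`), `members`
#'   (list), `loci` (list), `n_loci`, `total_len`.
#' @export
select_sanger_representative <- function(groups,
                                         curated_preferences = character()) {
  purrr::map_dfr(sort(unique(groups$species_id)), function(sp) {
    g <- groups[groups$species_id == sp, , drop = FALSE]
    rule <- NULL
    pref <- vapply(g$members, function(m)
      any(m %in% curated_preferences), logical(1))
    if (any(pref)) {
      g <- g[pref, , drop = FALSE]
      rule <- "curated"
    }
    s1 <- g$has_rbcL & g$n_loci >= 2L
    if (any(s1)) {
      cand <- g[s1, , drop = FALSE]
      pick <- cand[order_groups(cand), ][1, ]
      rule <- rule %||% "S1"
    } else if (any(g$has_rbcL)) {
      cand <- g[g$has_rbcL, , drop = FALSE]
      pick <- cand[order_groups(cand, key = cand$rbcL_len), ][1, ]
      rule <- rule %||% "S2"
    } else {
      pick <- g[order_groups(g), ][1, ]
      rule <- rule %||% "S3"
    }
    tibble::tibble(species_id = sp, rule = rule, members = pick$members,
                   loci = pick$loci, n_loci = pick$n_loci,
                   total_len = pick$total_len)
  })
}

#' Select one plastome representative per species
#'
#' Each plastome-derived specimen (one source accession) carries many
#' loci; per species the specimen with the greatest combined ungapped
#' length across all plastome loci is selected. Species selected here are
#' excluded from Sanger selection downstream.
#'
#' @param records Plastome-tier records: `accession` (the locus-level
#'   id), `specimen` (source accession id), `species_id`, `locus`, `seq`.
#' @return A tibble: `species_id`, `specimen`, `rule` (`"plastome"`),
#'   `members` (list: locus -> accession), `n_loci`, `total_len`.
#' @export
select_plastome_representative <- function(records) {
  records$len <- ungapped_length(records$seq)
  purrr::map_dfr(sort(unique(records$species_id)), function(sp) {
    rows <- records[records$species_id == sp, , drop = FALSE]
    by_spec <- rows |>
      dplyr::group_by(.data$specimen) |>
      dplyr::summarise(total_len = sum(.data$len), n_loci = dplyr::n(),
                       .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$total_len), .data$specimen)
    best <- by_spec$specimen[1]
    brows <- rows[rows$specimen == best, , drop = FALSE]
    tibble::tibble(species_id = sp, specimen = best, rule = "plastome",
                   members = list(stats::setNames(brows$accession, brows$locus)),
                   n_loci = nrow(brows),
                   total_len = by_spec$total_len[1])
  })
}

#' Write a selection result as TSV
#'
#' One row per (species, locus): `species_id`, `rule`, `locus`,
#' `accession`.
#'
#' @param selection Output of [select_sanger_representative()] or
#'   [select_plastome_representative()].
#' @param path Output path.
#' @export
write_selection <- function(selection, path) {
  flat <- purrr::map_dfr(seq_len(nrow(selection)), function(i) {
    m <- selection$members[[i]]
    tibble::tibble(species_id = selection$species_id[i],
                   rule = selection$rule[i],
                   locus = names(m), accession = unname(m))
  })
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
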