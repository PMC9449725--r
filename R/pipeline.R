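#' Run the full curation pipeline on an input bundle
#'
#' Chains every stage on a bundle shaped like [make_toy_dataset()]
#' output: name resolution of raw organism names against the taxonomy,
#' admissibility filtering, rogue detection from the all-by-all hit
#' table, curated exclude/include lists, species-monophyly
#' classification from the gene trees, candidate concatenation grouping
#' and representative selection (plastome species first, then Sanger),
#' supermatrix concatenation over the selected records, and fossil
#' calibration compilation (root-and-trim, node assignment, redundancy
#' resolution, dating-config emission).
#'
#' @param bundle A list with elements `taxonomy`, `records`,
#'   `inadmissible` (optional), `plastome_records` (optional), `hits`,
#'   `gene_trees`, `species_tree`, `outgroup`, `calibrations`.
#' @param exclude_list,include_list Curated accession lists (see
#'   [apply_curated_lists()]).
#' @param root_age Fixed root age (Ma) for the dating configuration.
#' @param smoothing Smoothing value written into the returned config.
#' @return A list: `resolution` (accession -> accepted species id),
#'   `admissibility`, `rogues` (rogue report), `monophyly`,
#'   `selection_sanger`, `selection_plastome`, `supermatrix`,
#'   `calibration` (list: `tree`, `assigned`, `unassignable`, `kept`,
#'   `superseded`, `config`).
#' @export
run_pipeline <- function(bundle, exclude_list = character(),
                         include_list = character(),
                         root_age = 475, smoothing = 1e-12) {
  taxonomy <- bundle$taxonomy
  stopifnot(nrow(validate_taxonomy(taxonomy)) == 0L)

  # 1. admissibility on the union of records
  all_records <- dplyr::bind_rows(bundle$records, bundle$inadmissible)
  adm <- filter_admissible(all_records)
  records <- adm$kept

  # 2. name resolution
  resolution <- vapply(records$raw_name, function(nm) {
    m <- match_name(nm, taxonomy)
    if (m$match_kind %in% c("none", "ambiguous")) NA_character_
    else resolve_accepted(m, taxonomy)
  }, character(1), USE.NAMES = FALSE)
  records$species_id <- resolution
  records <- records[!is.na(records$species_id), , drop = FALSE]
  res_map <- stats::setNames(records$species_id, records$accession)

  # 3. rogue detection on the all-by-all table
  rogues <- detect_rogues(bundle$hits, res_map, taxonomy)
  flagged <- rogues$accession[rogues$flagged]
  records <- apply_curated_lists(records,
                                 exclude_list = union(exclude_list, flagged),
                                 include_list = include_list)

  # 4. monophyly from gene trees (rogue tips may still sit in the trees;
  # only surviving accessions are classified)
  trees <- lapply(bundle$gene_trees, function(tr)
    ape::keep.tip(tr, intersect(tr$tip.label, records$accession)))
  trees <- trees[vapply(trees, function(t) length(t$tip.label) >= 3,
                        logical(1))]
  mono <- classify_species_monophyly(trees, res_map)

  # 5. selection: plastome first, those species leave the Sanger pool
  plastome <- bundle$plastome_records
  sel_plast <- if (!is.null(plastome) && nrow(plastome) > 0L) {
    select_plastome_representative(plastome)
  } else NULL
  sanger_pool <- records[!records$species_id %in%
                           (sel_plast$species_id %||% character()), ,
                         drop = FALSE]
  groups <- build_concat_groups(sanger_pool, mono)
  sel <- select_sanger_representative(
    groups, curated_preferences = sanger_pool$accession[sanger_pool$preferred])

  # 6. supermatrix over the selected Sanger records (fixture sequences
  # are unaligned but equal-length per locus, so they concatenate as-is)
  chosen <- purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    m <- sel$members[[i]]
    tibble::tibble(species_id = sel$species_id[i], locus = names(m),
                   accession = unname(m))
  })
  chosen <- dplyr::left_join(chosen,
    dplyr::select(records, "accession", "locus", "seq"),
    by = c("accession", "locus"))
  alns <- lapply(split(chosen, chosen$locus), function(d) {
    w <- max(nchar(d$seq))
    padded <- vapply(d$seq, function(s)
      paste0(s, strrep("?", w - nchar(s))), character(1))
    locus_alignment(stats::setNames(padded, d$species_id), d$locus[1])
  })
  supermatrix <- concatenate_supermatrix(unname(alns),
                                         locus_order = sort(names(alns)))

  # 7. calibrations on the rooted, outgroup-trimmed species tree
  cal_tree <- root_and_trim(bundle$species_tree, bundle$outgroup)
  asg <- assign_calibration_nodes(cal_tree, bundle$calibrations)
  dedup <- resolve_redundant_calibrations(asg$assigned)
  config <- write_treepl_config(
    dedup$kept, numsites = nchar(supermatrix$alignment$seqs[1]),
    smoothing = smoothing, fix_root = TRUE, root_age = root_age,
    tree = cal_tree)

  list(resolution = res_map, admissibility = adm, rogues = rogues,
       monophyly = mono, selection_sanger = sel,
       selection_plastome = sel_plast, supermatrix = supermatrix,
       calibration = list(tree = cal_tree, assigned = asg$assigned,
                          unassignable = asg$unassignable,
                          kept = dedup$kept, superseded = dedup$superseded,
                          config = config))
}
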