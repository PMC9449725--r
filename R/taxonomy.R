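#' Parse a scientific name into canonical and authorship parts
#'
#' Splits a raw name string into genus, epithet(s), infraspecific rank and
#' authorship, and flags qualifiers commonly found in sequence-repository
#' organism fields: open nomenclature annotations (`aff.`, `cf.`),
#' environmental/uncultured samples, and hybrid formulas (two names joined
#' by a multiplication sign or "x" separator). Parenthetical basionym
#' authors are detected so that author-format differences (present vs.
#' absent basionym author) do not affect the canonical part.
#'
#' Named hybrids written with a hybrid sign attached to a single name
#' (e.g. "xCystocarpium") are *not* formulas and parse as ordinary names.
#'
#' @param raw A single character string, e.g. `"Asplenium nidus L."`.
#' @return A list of class `parsed_name` with elements `genus`, `epithet`,
#'   `infraspecific_rank`, `infraspecific_epithet`, `authorship`, `canonical`
#'   (genus + epithets, no author tokens), `has_basionym_author`,
#'   `is_hybrid_formula`, and `annotation` (one of `"none"`, `"aff"`,
#'   `"cf"`, `"environmental"`).
#' @examples
#' parse_scientific_name("Asplenium nidus L.")
#' parse_scientific_name("Amauropelta sp. aff. rudis")
#' @export
parse_scientific_name <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- stringr::str_squish(raw)
  if (!nzchar(s)) {
    stop("parse failure: empty name after whitespace normalization", call. = FALSE)
  }

  annotation <- "none"
  if (stringr::str_detect(s, stringr::regex("environmental|uncultured", ignore_case = TRUE))) {
    annotation <- "environmental"
  } else if (stringr::str_detect(s, "(^|\\s)aff\\.?(\\s|$)")) {
    annotation <- "aff"
  } else if (stringr::str_detect(s, "(^|\\s)cf\\.?(\\s|$)")) {
    annotation <- "cf"
  }

  # hybrid formula: two names joined by a multiplication sign or a free-standing x
  is_formula <- stringr::str_detect(s, "\\s×\\s") ||
    stringr::str_detect(s, "\\s[xX]\\s+[A-Z×]")

  # strip annotation tokens before structural parsing
  s2 <- stringr::str_remove_all(s, "(^|\\s)(sp\\.|aff\\.?|cf\\.?)(?=\\s|$)")
  s2 <- stringr::str_squish(s2)

  toks <- stringr::str_split_1(s2, "\\s+")
  genus_tok <- toks[stringr::str_detect(toks, "^×?[A-Z][a-zéë-]+$")][1]
  if (is.na(genus_tok)) {
    if (annotation == "environmental") {
      # environmental/uncultured samples often have no parseable name;
      # the annotation alone is what downstream filtering needs
      return(structure(list(
        genus = NA_character_, epithet = NA_character_,
        infraspecific_rank = NA_character_,
        infraspecific_epithet = NA_character_, authorship = "",
        canonical = s, has_basionym_author = FALSE,
        is_hybrid_formula = is_formula, annotation = annotation
      ), class = "parsed_name"))
    }
    stop("parse failure: no capitalized genus token in '", raw, "'", call. = FALSE)
  }
  gi <- which(toks == genus_tok)[1]
  toks <- toks[gi:length(toks)]
  genus <- sub("^×", "", toks[1])

  lower_epithet <- function(x) {
    !is.na(x) && stringr::str_detect(x, "^×?[a-z][a-zéë-]+$") &&
      !x %in% c("var", "subsp", "ssp", "f", "forma", "x")
  }
  epithet <- NA_character_
  infra_rank <- NA_character_
  infra_epithet <- NA_character_
  i <- 2L
  if (i <= length(toks) && lower_epithet(toks[i])) {
    epithet <- sub("^×", "", toks[i])
    i <- i + 1L
    # infraspecific: "var. x", "subsp. x", "f. x"
    if (i + 1L <= length(toks) &&
        stringr::str_detect(toks[i], "^(var\\.?|subsp\\.?|ssp\\.?|f\\.?|forma)$") &&
        lower_epithet(toks[i + 1L])) {
      infra_rank <- sub("\\.$", "", toks[i])
      infra_rank <- c(ssp = "subsp", forma = "f")[infra_rank] %||% infra_rank
      infra_epithet <- toks[i + 1L]
      i <- i + 2L
    }
  }
  authorship <- if (i <= length(toks)) paste(toks[i:length(toks)], collapse = " ") else ""

  canonical <- paste(stats::na.omit(c(genus, epithet,
    if (!is.na(infra_rank)) paste0(infra_rank, "."), infra_epithet)), collapse = " ")

  structure(list(
    genus = genus,
    epithet = epithet,
    infraspecific_rank = infra_rank,
    infraspecific_epithet = infra_epithet,
    authorship = authorship,
    canonical = canonical,
    has_basionym_author = stringr::str_detect(authorship, "^\\("),
    is_hybrid_formula = is_formula,
    annotation = annotation
  ), class = "parsed_name")
}

#' @export
print.parsed_name <- function(x, ...) {
  cat("<parsed_name> ", x$canonical,
      if (nzchar(x$authorship)) paste0(" [", x$authorship, "]"),
      if (x$is_hybrid_formula) " (hybrid formula)",
      if (x$annotation != "none") paste0(" (", x$annotation, ")"), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

# canonical name (no authorship) of a taxonomy row
tax_canonical <- function(taxonomy) taxonomy$scientific_name

normalize_author <- function(a) {
  a <- stringr::str_remove_all(a, "[()\\.,]")
  stringr::str_squish(tolower(a))
}

#' Match a parsed name against a reference taxonomy
#'
#' Resolution proceeds in three stages: exact match on canonical name plus
#' authorship; exact match on canonical name alone; fuzzy match on the
#' canonical name by Levenshtein edit distance up to `max_distance`. At
#' equal canonical distance, candidates are ranked by similarity of
#' normalized authorship (case, punctuation and basionym parentheses
#' stripped) so that author-format differences break ties without ever
#' blocking a match. Remaining ties are reported as ambiguous, never
#' auto-resolved. Names with an infraspecific epithet are only compared
#' against taxonomy names that also have one (and vice versa), so a
#' trinomial never fuzzily collapses onto a binomial.
#'
#' @param query A `parsed_name` (from [parse_scientific_name()]) or a raw
#'   string.
#' @param taxonomy A taxonomy table as returned by [read_dwc_taxonomy()].
#' @param max_distance Maximum Levenshtein distance for fuzzy matching.
#'   The default scales with name length: one edit allowed per 10
#'   characters of the canonical name, capped at 3.
#' @return A list of class `name_match`: `query`, `matched_id`,
#'   `resolved_accepted_id`, `match_kind` (one of `exact_full`,
#'   `exact_canonical`, `fuzzy`, `none`, `ambiguous`) and `distance`.
#' @export
match_name <- function(query, taxonomy, max_distance = NULL) {
  if (is.character(query)) query <- parse_scientific_name(query)
  stopifnot(inherits(query, "parsed_name"))
  if (nrow(taxonomy) == 0L) stop("empty taxonomy", call. = FALSE)
  if (is.null(max_distance)) {
    max_distance <- min(3L, nchar(query$canonical) %/% 10L)
  }
  stopifnot(max_distance >= 0)

  res <- function(kind, id = NA_character_, dist = NA_integer_) {
    acc <- NA_character_
    if (!is.na(id)) {
      row <- taxonomy[taxonomy$taxon_id == id, ]
      acc <- if (row$status == "synonym") row$accepted_id else row$taxon_id
    }
    structure(list(query = query, matched_id = id, resolved_accepted_id = acc,
                   match_kind = kind, distance = dist), class = "name_match")
  }

  canon <- tax_canonical(taxonomy)
  # 1. exact full-name
  full_hit <- which(canon == query$canonical &
                      taxonomy$authorship == query$authorship)
  if (length(full_hit) == 1L) return(res("exact_full", taxonomy$taxon_id[full_hit], 0L))
  if (length(full_hit) > 1L) return(res("ambiguous", dist = 0L))

  # 2. exact canonical
  can_hit <- which(canon == query$canonical)
  if (length(can_hit) > 1L) {
    # tie-break on author similarity
    can_hit <- author_tiebreak(query, taxonomy, can_hit)
    if (length(can_hit) != 1L) return(res("ambiguous", dist = 0L))
    return(res("exact_canonical", taxonomy$taxon_id[can_hit], 0L))
  }
  if (length(can_hit) == 1L) return(res("exact_canonical", taxonomy$taxon_id[can_hit], 0L))

  if (max_distance == 0L) return(res("none"))

  # 3. fuzzy on canonical, restricted to same trinomial/binomial structure
  q_tri <- !is.na(query$infraspecific_epithet)
  t_tri <- stringr::str_count(canon, "\\s+") >= 2
  pool <- which(t_tri == q_tri)
  if (length(pool) == 0L) return(res("none"))
  d <- utils::adist(query$canonical, canon[pool])[1, ]
  dmin <- min(d)
  if (dmin > max_distance) return(res("none"))
  best <- pool[d == dmin]
  if (length(best) > 1L) best <- author_tiebreak(query, taxonomy, best)
  if (length(best) != 1L) return(res("ambiguous", dist = as.integer(dmin)))
  res("fuzzy", taxonomy$taxon_id[best], as.integer(dmin))
}

author_tiebreak <- function(query, taxonomy, idx) {
  qa <- normalize_author(query$authorship)
  ca <- vapply(taxonomy$authorship[idx], normalize_author, character(1))
  if (!nzchar(qa)) return(idx)  # nothing to compare
  d <- utils::adist(qa, ca)[1, ]
  sim <- 1 - d / pmax(nchar(qa), nchar(ca), 1)
  idx[sim == max(sim)]
}

#' @export
print.name_match <- function(x, ...) {
  cat("<name_match> ", x$query$canonical, " -> ", x$match_kind,
      if (!is.na(x$matched_id)) paste0(" (", x$matched_id,
        ", accepted ", x$resolved_accepted_id, ", d=", x$distance, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Resolve a name match to its accepted taxon
#'
#' Synonyms resolve in one hop via `accepted_id` (taxonomies validated by
#' [validate_taxonomy()] contain no synonym chains). Matches of kind
#' `none` or `ambiguous` fail with a reason code.
#'
#' @param match A `name_match` from [match_name()].
#' @param taxonomy The same taxonomy the match was produced from.
#' @return The accepted `taxon_id` (character scalar).
#' @export
resolve_accepted <- function(match, taxonomy) {
  stopifnot(inherits(match, "name_match"))
  if (match$match_kind %in% c("none", "ambiguous")) {
    stop("cannot resolve: match_kind=", match$match_kind,
         " (reason=", match$match_kind, ")", call. = FALSE)
  }
  id <- match$resolved_accepted_id
  if (!id %in% taxonomy$taxon_id) {
    stop("accepted id ", id, " not in taxonomy", call. = FALSE)
  }
  id
}

#' Validate a Darwin Core taxonomy table
#'
#' Checks the structural invariants every downstream operation relies on:
#' unique `taxon_id`s; every synonym's `accepted_id` points at an existing
#' accepted record (no dangling pointers, no synonym-to-synonym chains);
#' `parent_id` links exist and are acyclic. Violations are returned as
#' data, one row each, never raised as errors.
#'
#' @param taxonomy A taxonomy tibble (see [read_dwc_taxonomy()]).
#' @return A tibble with columns `taxon_id`, `kind`, `detail`; zero rows
#'   iff the taxonomy is valid.
#' @export
validate_taxonomy <- function(taxonomy) {
  v <- list()
  add <- function(id, kind, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(taxon_id = id, kind = kind, detail = detail)
  }
  dup <- unique(taxonomy$taxon_id[duplicated(taxonomy$taxon_id)])
  for (id in dup) add(id, "duplicate_id", "taxon_id appears more than once")

  ids <- taxonomy$taxon_id
  status <- stats::setNames(taxonomy$status, ids)
  for (i in seq_len(nrow(taxonomy))) {
    row <- taxonomy[i, ]
    if (row$status == "synonym") {
      if (is.na(row$accepted_id) || !nzchar(row$accepted_id)) {
        add(row$taxon_id, "dangling_accepted", "synonym with empty accepted_id")
      } else if (!row$accepted_id %in% ids) {
        add(row$taxon_id, "dangling_accepted",
            paste0("accepted_id ", row$accepted_id, " not found"))
      } else if (status[[row$accepted_id]] != "accepted") {
        add(row$taxon_id, "synonym_chain",
            paste0("accepted_id ", row$accepted_id, " is itself a synonym"))
      }
    }
    if (!is.na(row$parent_id) && nzchar(row$parent_id) &&
        !row$parent_id %in% ids) {
      add(row$taxon_id, "dangling_parent",
          paste0("parent_id ", row$parent_id, " not found"))
    }
  }
  # parent cycles
  parent <- stats::setNames(taxonomy$parent_id, ids)
  for (id in ids) {
    seen <- character()
    cur <- id
    while (!is.na(cur) && nzchar(cur) && cur %in% ids) {
      if (cur %in% seen) { add(id, "parent_cycle",
        paste0("cycle through ", cur)); break }
      seen <- c(seen, cur)
      cur <- parent[[cur]] %||% NA_character_
    }
  }
  out <- dplyr::bind_rows(v)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(taxon_id = character(), kind = character(), detail = character())
  }
  dplyr::distinct(out)
}

#' Apply edits to a taxonomy as a validated transaction
#'
#' Adds or replaces rows, then re-validates; if any violation is
#' introduced, the edit is rejected and the original table returned
#' unchanged with an error. There is no silent in-place mutation.
#'
#' @param taxonomy A taxonomy tibble.
#' @param edits A tibble of rows in the same schema; rows whose
#'   `taxon_id` already exists replace the existing row.
#' @return The edited, validated taxonomy.
#' @export
edit_taxonomy <- function(taxonomy, edits) {
  out <- dplyr::bind_rows(
    taxonomy[!taxonomy$taxon_id %in% edits$taxon_id, ],
    edits
  )
  viol <- validate_taxonomy(out)
  if (nrow(viol) > 0L) {
    stop("taxonomy edit rejected: ", nrow(viol), " violation(s), first: ",
         viol$kind[1], " at ", viol$taxon_id[1], call. = FALSE)
  }
  out
}

#' Full lineage of an accepted species
#'
#' Walks `parent_id` links from a species up to its order, reporting the
#' names at genus, family, suborder (if present in the chain) and order
#' rank. `is_monotypic_family` is computed on the fly as whether the
#' species' family contains exactly one accepted species.
#'
#' @param species_taxon_id taxon_id of an accepted species record.
#' @param taxonomy A validated taxonomy tibble.
#' @return A list of class `lineage` with `species_id`, `species`,
#'   `genus`, `family`, `suborder` (may be `NA`), `order`,
#'   `is_monotypic_family`.
#' @export
lineage_of <- function(species_taxon_id, taxonomy) {
  row <- taxonomy[taxonomy$taxon_id == species_taxon_id, ]
  if (nrow(row) != 1L || row$status != "accepted" || row$rank != "species") {
    stop(species_taxon_id, " is not an accepted species", call. = FALSE)
  }
  chain <- list()
  cur <- row
  while (TRUE) {
    chain[[cur$rank]] <- cur
    if (cur$rank == "order") break
    pid <- cur$parent_id
    if (is.na(pid) || !nzchar(pid)) {
      stop("broken parent chain above ", cur$taxon_id,
           " (", cur$scientific_name, "): no parent before order rank",
           call. = FALSE)
    }
    nxt <- taxonomy[taxonomy$taxon_id == pid, ]
    if (nrow(nxt) != 1L) {
      stop("broken parent chain: missing ancestor ", pid, call. = FALSE)
    }
    cur <- nxt
  }
  fam_id <- chain[["family"]]$taxon_id %||% NA_character_
  n_in_family <- if (is.na(fam_id)) NA_integer_ else {
    count_species_under(fam_id, taxonomy)
  }
  structure(list(
    species_id = species_taxon_id,
    species = row$scientific_name,
    genus = chain[["genus"]]$scientific_name %||% NA_character_,
    family = chain[["family"]]$scientific_name %||% NA_character_,
    suborder = chain[["suborder"]]$scientific_name %||% NA_character_,
    order = chain[["order"]]$scientific_name,
    is_monotypic_family = if (is.na(n_in_family)) NA else n_in_family == 1L
  ), class = "lineage")
}

count_species_under <- function(ancestor_id, taxonomy) {
  parent <- stats::setNames(taxonomy$parent_id, taxonomy$taxon_id)
  sp <- taxonomy[taxonomy$rank == "species" & taxonomy$status == "accepted", ]
  n <- 0L
  for (i in seq_len(nrow(sp))) {
    cur <- sp$taxon_id[i]
    while (!is.na(cur) && nzchar(cur)) {
      if (cur == ancestor_id) { n <- n + 1L; break }
      cur <- parent[[cur]] %||% NA_character_
    }
  }
  n
}

#' Lineages for many species at once
#'
#' @param species_ids character vector of accepted species taxon_ids.
#' @param taxonomy A validated taxonomy tibble.
#' @return A tibble with one row per species: `species_id`, `species`,
#'   `genus`, `family`, `suborder`, `order`, `is_monotypic_family`.
#' @export
lineage_table <- function(species_ids, taxonomy) {
  purrr::map_dfr(unique(species_ids), function(id) {
    l <- lineage_of(id, taxonomy)
    tibble::tibble(species_id = l$species_id, species = l$species,
                   genus = l$genus, family = l$family,
                   suborder = l$suborder, order = l$order,
                   is_monotypic_family = l$is_monotypic_family)
  })
}

#' Read / write Darwin Core taxonomy tables
#'
#' The on-disk format is TSV or CSV with Darwin Core headers `taxonID`,
#' `scientificName`, `scientificNameAuthorship`, `taxonRank`,
#' `taxonomicStatus`, `acceptedNameUsageID`, `parentNameUsageID` (UTF-8).
#' In memory the package uses snake_case columns `taxon_id`,
#' `scientific_name`, `authorship`, `rank`, `status`, `accepted_id`,
#' `parent_id`.
#'
#' @param path File path; delimiter inferred from the extension
#'   (".csv" = comma, otherwise tab).
#' @return `read_dwc_taxonomy()`: a taxonomy tibble.
#' @export
read_dwc_taxonomy <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          na.strings = c("NA", ""), fileEncoding = "UTF-8")
  need <- c("taxonID", "scientificName", "taxonomicStatus",
            "acceptedNameUsageID", "parentNameUsageID", "taxonRank")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("missing Darwin Core columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    taxon_id = as.character(df$taxonID),
    scientific_name = df$scientificName,
    authorship = if ("scientificNameAuthorship" %in% names(df)) {
      dplyr::coalesce(df$scientificNameAuthorship, "")
    } else "",
    rank = df$taxonRank,
    status = df$taxonomicStatus,
    accepted_id = as.character(df$acceptedNameUsageID),
    parent_id = as.character(df$parentNameUsageID)
  )
}

#' @rdname read_dwc_taxonomy
#' @param taxonomy A taxonomy tibble.
#' @export
write_dwc_taxonomy <- function(taxonomy, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(
    taxonID = taxonomy$taxon_id,
    scientificName = taxonomy$scientific_name,
    scientificNameAuthorship = taxonomy$authorship,
    taxonRank = taxonomy$rank,
    taxonomicStatus = taxonomy$status,
    acceptedNameUsageID = taxonomy$accepted_id,
    parentNameUsageID = taxonomy$parent_id,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = sep, quote = TRUE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a taxonomy violations report
#'
#' @param violations Output of [validate_taxonomy()].
#' @param path Output TSV path.
#' @export
write_violations <- function(violations, path) {
  utils::write.table(violations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
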