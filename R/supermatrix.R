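#' Construct a locus alignment object
#'
#' A lightweight container for one locus: named, equal-length sequences
#' over `A,C,G,T,N,?,-` with unique taxa.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param locus Locus name.
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(seqs, locus = "locus") {
  stopifnot(is.character(seqs), length(seqs) >= 1L,
            !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  structure(list(locus = locus, taxa = names(seqs), seqs = seqs),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus, ": ", length(x$taxa), " taxa x ",
      nchar(x$seqs[1]), " columns\n", sep = "")
  invisible(x)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
}

matrix_to_aln <- function(m, taxa, locus) {
  locus_alignment(stats::setNames(apply(m, 1L, paste, collapse = ""), taxa),
                  locus)
}

#' Remove gap-rich alignment columns
#'
#' Drops every column whose gap fraction — the fraction of rows holding
#' `"-"` — strictly exceeds `max_gap_fraction`; a column exactly at the
#' threshold is kept. Only `"-"` counts as a gap here; `"N"` and `"?"`
#' are missing data for accounting purposes but do not trigger trimming
#' (gap-threshold semantics of the usual alignment trimmers). Typical
#' thresholds are 0.05 for coding loci and 0.01 for spacers.
#'
#' @param aln A `locus_alignment`.
#' @param max_gap_fraction Number in \[0, 1\].
#' @return The trimmed `locus_alignment`; removed 1-based column indices
#'   in `attr(, "removed_columns")`.
#' @export
trim_gappy_columns <- function(aln, max_gap_fraction) {
  stopifnot(inherits(aln, "locus_alignment"),
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  m <- aln_matrix(aln)
  if (ncol(m) == 0L) stop("empty alignment", call. = FALSE)
  gap_frac <- colMeans(m == "-")
  drop <- which(gap_frac > max_gap_fraction)
  keep <- setdiff(seq_len(ncol(m)), drop)
  out <- matrix_to_aln(m[, keep, drop = FALSE], aln$taxa, aln$locus)
  attr(out, "removed_columns") <- drop
  out
}

#' Plan spacer-region subalignments for a merge-capable aligner
#'
#' Spacer regions align poorly across families, so they are aligned per
#' family and merged. Families with at least `min_group` sampled species
#' become their own subalignment group; species of smaller families enter
#' the merge as singletons. Families on the exclusion list (by default
#' Anemiaceae, whose spacers carry too many indels to align reliably) and
#' all outgroup species are dropped with reasons.
#'
#' @param species Character vector of species taxon_ids sampled for the
#'   spacer locus.
#' @param taxonomy A validated taxonomy tibble.
#' @param min_group Minimum family size for a subalignment group.
#' @param excluded_families Families dropped entirely.
#' @param outgroup_species Species taxon_ids designated as outgroup.
#' @return A list of class `subalignment_plan`: `groups` (named list
#'   family -> species vector), `singletons` (species vector), `excluded`
#'   (tibble `id`, `reason`).
#' @export
plan_spacer_subalignments <- function(species, taxonomy, min_group = 3L,
                                      excluded_families = "Anemiaceae",
                                      outgroup_species = character()) {
  species <- unique(species)
  excl <- list()
  og <- intersect(species, outgroup_species)
  if (length(og) > 0L) {
    excl[[length(excl) + 1L]] <- tibble::tibble(id = og, reason = "outgroup")
  }
  species <- setdiff(species, og)
  lin <- lineage_table(species, taxonomy)
  in_excl_fam <- lin$species_id[lin$family %in% excluded_families]
  if (length(in_excl_fam) > 0L) {
    excl[[length(excl) + 1L]] <-
      tibble::tibble(id = in_excl_fam, reason = "unalignable_family")
  }
  lin <- lin[!lin$species_id %in% in_excl_fam, , drop = FALSE]
  counts <- table(lin$family)
  big <- names(counts)[counts >= min_group]
  groups <- lapply(stats::setNames(big, big), function(f)
    sort(lin$species_id[lin$family == f]))
  singletons <- sort(lin$species_id[!lin$family %in% big])
  excluded <- if (length(excl) > 0L) dplyr::bind_rows(excl) else
    tibble::tibble(id = character(), reason = character())
  structure(list(groups = groups[order(names(groups))],
                 singletons = singletons,
                 excluded = excluded),
            class = "subalignment_plan")
}

#' Write a subalignment merge table
#'
#' The whitespace-separated table of 1-based sequence indices consumed by
#' merge-capable aligners: one row per subalignment group, indices
#' referring to positions in the concatenated input file (groups first,
#' in plan order, then singletons).
#'
#' @param plan A `subalignment_plan`.
#' @param path Output path.
#' @return Invisibly, the ordered sequence ids (group members then
#'   singletons) matching the emitted indices.
#' @export
write_merge_table <- function(plan, path) {
  ordered <- c(unlist(plan$groups, use.names = FALSE), plan$singletons)
  idx <- stats::setNames(seq_along(ordered), ordered)
  lines <- vapply(plan$groups, function(g)
    paste(idx[g], collapse = " "), character(1))
  writeLines(unname(lines), path)
  invisible(ordered)
}

#' Concatenate locus alignments into a partitioned supermatrix
#'
#' Taxa are the union across loci (lexicographic order); a taxon absent
#' from a locus receives a block of `"?"`. Partitions are contiguous,
#' non-overlapping 1-based inclusive column ranges covering the matrix in
#' the given locus order. Missing fractions count cells in
#' `{"?", "N", "-"}`.
#'
#' @param alignments List of `locus_alignment` objects.
#' @param locus_order Character vector ordering the loci (default: the
#'   order given).
#' @return A list of class `supermatrix_bundle`: `alignment`
#'   (`locus_alignment` of the concatenation), `partitions` (tibble
#'   `locus`, `start`, `end`), `missing_by_locus` (named numeric),
#'   `missing_overall` (numeric).
#' @export
concatenate_supermatrix <- function(alignments,
                                    locus_order = NULL) {
  if (length(alignments) == 0L) stop("empty locus list", call. = FALSE)
  names(alignments) <- vapply(alignments, function(a) a$locus, character(1))
  if (is.null(locus_order)) locus_order <- names(alignments)
  stopifnot(setequal(locus_order, names(alignments)))
  alignments <- alignments[locus_order]
  for (a in alignments) {
    if (anyDuplicated(a$taxa)) {
      stop("duplicated taxon within locus ", a$locus, call. = FALSE)
    }
  }
  taxa <- sort(unique(unlist(lapply(alignments, function(a) a$taxa))))
  widths <- vapply(alignments, function(a) nchar(a$seqs[1]), integer(1))
  ends <- unname(cumsum(widths))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  blocks <- lapply(alignments, function(a) {
    w <- nchar(a$seqs[1])
    s <- stats::setNames(rep(strrep("?", w), length(taxa)), taxa)
    s[a$taxa] <- unname(a$seqs)
    s
  })
  concat <- Reduce(function(x, y) paste0(x, y), blocks)
  names(concat) <- taxa
  missing_frac <- function(seqs) {
    chars <- unlist(strsplit(seqs, "", fixed = TRUE))
    mean(toupper(chars) %in% c("?", "N", "-"))
  }
  structure(list(
    alignment = locus_alignment(concat, "supermatrix"),
    partitions = tibble::tibble(locus = locus_order,
                                start = starts, end = unname(ends)),
    missing_by_locus = vapply(blocks, missing_frac, numeric(1)),
    missing_overall = missing_frac(concat)
  ), class = "supermatrix_bundle")
}

#' @export
print.supermatrix_bundle <- function(x, ...) {
  cat("<supermatrix_bundle> ", length(x$alignment$taxa), " taxa x ",
      nchar(x$alignment$seqs[1]), " columns, ", nrow(x$partitions),
      " partitions, ", sprintf("%.1f%%", 100 * x$missing_overall),
      " missing\n", sep = "")
  invisible(x)
}

#' Slice one partition back out of a supermatrix
#'
#' @param bundle A `supermatrix_bundle`.
#' @param locus Locus name.
#' @param drop_missing_taxa Drop taxa whose block is entirely `"?"`.
#' @return A `locus_alignment`.
#' @export
slice_partition <- function(bundle, locus, drop_missing_taxa = TRUE) {
  p <- bundle$partitions[bundle$partitions$locus == locus, ]
  stopifnot(nrow(p) == 1L)
  seqs <- substr(bundle$alignment$seqs, p$start, p$end)
  names(seqs) <- bundle$alignment$taxa
  if (drop_missing_taxa) {
    seqs <- seqs[seqs != strrep("?", p$end - p$start + 1L)]
  }
  locus_alignment(seqs, locus)
}

#' Alignment and partition file I/O
#'
#' FASTA wraps at 80 columns; the partition file uses the widely parsed
#' `DNA, <locus> = <start>-<end>` dialect; relaxed PHYLIP puts each
#' taxon name and sequence on one line.
#'
#' @param aln A `locus_alignment`.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$seqs)) {
    writeLines(paste0(">", aln$taxa[i]), con)
    s <- aln$seqs[i]
    starts <- seq(1L, nchar(s), by = 80L)
    writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @param locus Locus name for the returned alignment.
#' @export
read_alignment_fasta <- function(path, locus = "locus") {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  ids <- sub("^>", "", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  locus_alignment(stats::setNames(unname(seqs), ids), locus)
}

#' @rdname write_alignment_fasta
#' @export
write_alignment_phylip <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(aln$taxa), nchar(aln$seqs[1])), con)
  writeLines(paste(aln$taxa, unname(aln$seqs)), con)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @param partitions Partition tibble (`locus`, `start`, `end`).
#' @export
write_partition_file <- function(partitions, path) {
  writeLines(sprintf("DNA, %s = %d-%d", partitions$locus,
                     partitions$start, partitions$end), path)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
read_partition_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  m <- stringr::str_match(lines, "^DNA,\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)$")
  if (anyNA(m[, 1])) stop("unparseable partition line: ",
                          lines[which(is.na(m[, 1]))[1]], call. = FALSE)
  tibble::tibble(locus = m[, 2], start = as.integer(m[, 3]),
                 end = as.integer(m[, 4]))
}
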