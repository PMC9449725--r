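#' Default locus registry
#'
#' The packaged registry of target plastid loci: seven "Sanger" loci
#' commonly obtained by PCR (atpA, atpB, matK, rbcL, rps4, trnL-trnF,
#' rps4-trnS) and 79 "plastome" loci (77 single-copy protein-coding genes
#' plus the two intergenic spacers) typically mined from whole plastome
#' accessions. The five genes shared between the sets carry
#' `tier = "both"`. trnL-trnF is treated as a single locus (trnL intron +
#' 3' trnL exon + trnL-trnF spacer); it is not sub-segmented.
#'
#' @return A tibble with columns `name`, `category` (`coding`/`spacer`)
#'   and `tier` (`sanger`/`plastome`/`both`).
#' @export
default_loci <- function() {
  coding <- c(
    "atpA", "atpB", "atpE", "atpF", "atpH", "atpI",
    paste0("ndh", c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K")),
    "petA", "petB", "petD", "petG", "petL", "petN",
    "psaA", "psaB", "psaC", "psaI", "psaJ",
    paste0("psb", c("A", "B", "C", "D", "E", "F", "H", "I", "J", "K", "L", "M", "N", "T")),
    "rbcL",
    paste0("rpl", c(2, 14, 16, 20, 22, 23, 32, 33, 36)),
    "rpoA", "rpoB", "rpoC1", "rpoC2",
    paste0("rps", c(2, 3, 4, 7, 8, 11, 12, 14, 15, 18, 19)),
    "matK", "ccsA", "cemA", "clpP", "accD",
    "ycf1", "ycf2", "chlB", "chlL", "chlN"
  )
  spacers <- c("trnL-trnF", "rps4-trnS")
  sanger_only <- spacers
  shared <- c("atpA", "atpB", "matK", "rbcL", "rps4")
  tibble::tibble(
    name = c(coding, spacers),
    category = c(rep("coding", length(coding)), rep("spacer", 2L)),
    tier = dplyr::case_when(
      c(coding, spacers) %in% shared ~ "both",
      c(coding, spacers) %in% sanger_only ~ "both",
      TRUE ~ "plastome"
    )
  )
}

#' Sanger-tier locus names from a registry
#' @param registry A locus registry tibble (default [default_loci()]).
#' @return Character vector of the Sanger locus names.
#' @export
sanger_loci <- function(registry = default_loci()) {
  registry$name[registry$tier %in% c("sanger", "both")]
}

#' Plastome-tier locus names from a registry
#' @inheritParams sanger_loci
#' @export
plastome_loci <- function(registry = default_loci()) {
  registry$name[registry$tier %in% c("plastome", "both")]
}

#' Sequence length excluding missing bases
#'
#' Counts characters of a sequence that are not missing, where the missing
#' set is exactly `"?"`, `"N"`, `"-"` (case-insensitive for N). All
#' sequence-length comparisons in selection use this measure.
#'
#' @param seq Character vector of sequences over `A,C,G,T,N,?,-`
#'   (case-insensitive).
#' @return Integer vector of ungapped lengths.
#' @examples
#' ungapped_length(c("ACGT", "AC-N?"))  # 4, 2
#' @export
ungapped_length <- function(seq) {
  stopifnot(is.character(seq))
  vapply(seq, function(s) {
    if (!nzchar(s)) return(0L)
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    bad <- !chars %in% c("A", "C", "G", "T", "N", "?", "-")
    if (any(bad)) {
      stop("illegal character '", chars[which(bad)[1]], "' at position ",
           which(bad)[1], call. = FALSE)
    }
    sum(!chars %in% c("?", "N", "-"))
  }, integer(1), USE.NAMES = FALSE)
}

#' Filter accession records for admissibility
#'
#' Drops records whose organism name carries an open-nomenclature
#' annotation (`aff.`, `cf.`), marks an environmental/uncultured sample,
#' or is a hybrid formula. Hybrid taxa with standard (non-formula) names
#' are kept. Every drop carries a reason code; kept and dropped rows
#' partition the input.
#'
#' @param records A tibble of sequence records with a `raw_name` column.
#' @return A list with elements `kept` (tibble) and `dropped` (tibble with
#'   an extra `reason` column: `aff`, `cf`, `environmental`,
#'   `hybrid_formula`, or `unparseable`).
#' @export
filter_admissible <- function(records) {
  reason <- vapply(records$raw_name, function(nm) {
    p <- tryCatch(parse_scientific_name(nm), error = function(e) NULL)
    if (is.null(p)) return("unparseable")
    if (p$is_hybrid_formula) return("hybrid_formula")
    if (p$annotation != "none") return(p$annotation)
    ""
  }, character(1), USE.NAMES = FALSE)
  dropped <- records[reason != "", , drop = FALSE]
  dropped$reason <- reason[reason != ""]
  list(kept = records[reason == "", , drop = FALSE], dropped = dropped)
}

#' Classify a source accession as Sanger or plastome tier
#'
#' Repositories have no formal genomic-vs-Sanger flag, so tiering uses an
#' empirical total-length cutoff: accessions of 7,000 bp or less are
#' Sanger, longer ones plastome.
#'
#' @param source_accession_length Integer vector of total accession
#'   lengths (bp), each >= 1.
#' @return Character vector, `"sanger"` or `"plastome"`.
#' @export
classify_tier <- function(source_accession_length) {
  stopifnot(all(source_accession_length >= 1))
  ifelse(source_accession_length <= 7000, "sanger", "plastome")
}

#' Build per-genus reference databases
#'
#' For each locus, keeps a single representative per genus: the record
#' with the greatest ungapped length, ties broken by lexicographically
#' smallest accession. References are stored ungapped. Records whose
#' species cannot be placed in a genus are skipped with a log attribute.
#'
#' @param records Sequence-record tibble with columns `accession`,
#'   `locus`, `species_id`, `seq`.
#' @param taxonomy A validated taxonomy tibble.
#' @return A tibble (`locus`, `genus`, `accession`, `seq`) of class
#'   `reference_set`; skipped records in `attr(, "skipped")`.
#' @export
build_reference_db <- function(records, taxonomy) {
  lin <- lineage_table(unique(records$species_id[
    records$species_id %in% taxonomy$taxon_id]), taxonomy)
  recs <- dplyr::left_join(
    dplyr::select(tibble::as_tibble(records), -dplyr::any_of("genus")),
    dplyr::select(lin, "species_id", "genus"), by = "species_id")
  skipped <- recs[is.na(recs$genus), , drop = FALSE]
  recs <- recs[!is.na(recs$genus), , drop = FALSE]
  recs$seq <- gsub("-", "", recs$seq, fixed = TRUE)
  recs$len <- ungapped_length(recs$seq)
  out <- recs |>
    dplyr::group_by(.data$locus, .data$genus) |>
    dplyr::arrange(dplyr::desc(.data$len), .data$accession, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("locus", "genus", "accession", "seq") |>
    dplyr::arrange(.data$locus, .data$genus)
  attr(out, "skipped") <- skipped$accession
  class(out) <- c("reference_set", class(out))
  out
}

#' Reverse complement
#' @param seq Character vector of DNA strings.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Score and locate the best local alignment of a candidate against a
#' reference
#'
#' Smith-Waterman local alignment with the package's scoring scheme
#' (match +1, mismatch -1, gap -2, no affine opening cost).
#'
#' @param candidate,reference Single DNA strings.
#' @return List with `score`, `identity`, `q_start`, `q_end` (0-based
#'   half-open on the candidate).
#' @keywords internal
local_align <- function(candidate, reference) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(candidate),
    subject = Biostrings::DNAString(reference),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  rng <- Biostrings::pattern(al)
  list(score = Biostrings::score(al),
       identity = Biostrings::pid(al) / 100,
       q_start = Biostrings::start(rng) - 1L,
       q_end = Biostrings::end(rng))
}

#' Extraction parameters for the baited search
#'
#' @param min_score Minimum local-alignment score for a significant match.
#' @param min_identity Minimum identity fraction across the aligned span.
#' @return A list of parameters for [extract_locus()].
#' @export
extraction_params <- function(min_score = 50, min_identity = 0.7) {
  list(min_score = min_score, min_identity = min_identity)
}

#' Baited extraction of a target locus from a candidate sequence
#'
#' Aligns the candidate locally against every reference for the locus on
#' both strands, keeps the best-scoring reference, and, if the hit clears
#' the score and identity thresholds, returns the aligned span of the
#' candidate (reverse-complemented onto the plus strand when the hit is on
#' the minus strand). Absence of a significant match is a value (`NULL`),
#' not an error.
#'
#' @param candidate_seq A single DNA string.
#' @param references Reference tibble rows for one locus (columns
#'   `accession`, `seq`), e.g. a slice of [build_reference_db()] output.
#' @param params From [extraction_params()].
#' @param candidate_id Identifier used in the returned hit.
#' @return `NULL`, or a list with `hit` (query_id, ref_id, q_start, q_end
#'   0-based half-open, strand, score, identity) and `seq` (the extracted
#'   plus-strand subsequence).
#' @export
extract_locus <- function(candidate_seq, references,
                          params = extraction_params(),
                          candidate_id = "query") {
  stopifnot(nzchar(candidate_seq), nrow(references) >= 1L)
  best <- NULL
  for (i in seq_len(nrow(references))) {
    for (strand in c("+", "-")) {
      cand <- if (strand == "+") candidate_seq else revcomp(candidate_seq)
      al <- local_align(cand, references$seq[i])
      if (is.null(best) || al$score > best$score ||
          (al$score == best$score && references$accession[i] < best$ref_id)) {
        best <- c(al, list(ref_id = references$accession[i], strand = strand))
      }
    }
  }
  if (best$score < params$min_score || best$identity < params$min_identity) {
    return(NULL)
  }
  n <- nchar(candidate_seq)
  # map minus-strand span back to plus-strand coordinates
  if (best$strand == "-") {
    q_start <- n - best$q_end
    q_end <- n - best$q_start
  } else {
    q_start <- best$q_start
    q_end <- best$q_end
  }
  extracted <- substr(candidate_seq, q_start + 1L, q_end)
  if (best$strand == "-") extracted <- revcomp(extracted)
  list(
    hit = list(query_id = candidate_id, ref_id = best$ref_id,
               q_start = q_start, q_end = q_end, strand = best$strand,
               score = best$score, identity = best$identity),
    seq = extracted
  )
}

#' Extract a locus span from precomputed tabular hits
#'
#' The alternative extraction path: consumes rows of a similarity hit
#' table (1-based inclusive query coordinates, as in BLAST tabular
#' output) instead of aligning. For identical hits the two paths return
#' identical spans.
#'
#' @param candidate_seq A single DNA string.
#' @param hits A tibble with columns `qstart`, `qend`, `bitscore` (1-based
#'   inclusive; `qstart > qend` encodes a minus-strand hit).
#' @return The extracted plus-strand subsequence of the best-scoring row,
#'   reverse-complemented when the hit is on the minus strand.
#' @export
extract_from_hits <- function(candidate_seq, hits) {
  stopifnot(nrow(hits) >= 1L)
  best <- hits[order(-hits$bitscore), ][1, ]
  minus <- best$qstart > best$qend
  lo <- min(best$qstart, best$qend)
  hi <- max(best$qstart, best$qend)
  out <- substr(candidate_seq, lo, hi)
  if (minus) out <- revcomp(out)
  out
}

#' Normalize a voucher string
#'
#' Case-folds, strips punctuation and collapses internal whitespace, so
#' that "SMITH 123" and "Smith, 123" compare equal. Empty/NA stays NA:
#' absence of a voucher never counts as a shared voucher.
#'
#' @param voucher Character vector.
#' @return Normalized character vector with `NA` for missing.
#' @export
normalize_voucher <- function(voucher) {
  out <- stringr::str_squish(tolower(
    stringr::str_replace_all(voucher, "[[:punct:]]", " ")))
  out[is.na(out) | !nzchar(out)] <- NA_character_
  out
}

#' Build a publication key
#'
#' A citation key of the form `firstauthor_year_<hash>` from normalized
#' first author, year and a short hash of the normalized title, so that
#' records from one paper group together without exact string equality.
#'
#' @param first_author,year,title Character/numeric vectors.
#' @return Character vector of keys; `NA` where all fields are missing.
#' @export
publication_key <- function(first_author, year, title) {
  fa <- stringr::str_squish(tolower(stringr::str_replace_all(
    dplyr::coalesce(as.character(first_author), ""), "[[:punct:]]", "")))
  ti <- stringr::str_squish(tolower(stringr::str_replace_all(
    dplyr::coalesce(as.character(title), ""), "[[:punct:]]", "")))
  h <- vapply(ti, function(t) {
    if (!nzchar(t)) return("0")
    format(sum(utf8ToInt(t) * seq_len(nchar(t))) %% 99991L)
  }, character(1), USE.NAMES = FALSE)
  out <- paste(fa, dplyr::coalesce(as.character(year), ""), h, sep = "_")
  out[!nzchar(fa) & (is.na(year))] <- NA_character_
  out
}

# ---- sequence record I/O ----------------------------------------------------

#' Read and write FASTA with structured identifiers
#'
#' Sequence files use ids of the form `accession|locus|taxon_id`; lines
#' wrap at 80 columns.
#'
#' @param path File path.
#' @return `read_record_fasta()`: a tibble with `accession`, `locus`,
#'   `species_id`, `seq`.
#' @export
read_record_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- stringr::str_split_fixed(names(ss), stringr::fixed("|"), 3)
  tibble::tibble(accession = parts[, 1], locus = parts[, 2],
                 species_id = parts[, 3], seq = as.character(ss))
}

#' @rdname read_record_fasta
#' @param records Tibble with `accession`, `locus`, `species_id`, `seq`.
#' @export
write_record_fasta <- function(records, path) {
  ss <- Biostrings::DNAStringSet(records$seq)
  names(ss) <- paste(records$accession, records$locus, records$species_id,
                     sep = "|")
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read and write similarity hit tables (tabular, 12 columns)
#'
#' The classic 12-column tabular layout: qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore, with 1-based
#' inclusive coordinates.
#'
#' @param path File path (TSV, no header).
#' @return `read_hit_table()`: a tibble with those 12 columns.
#' @export
read_hit_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, col.names = cols)
  tibble::as_tibble(df)
}

#' @rdname read_hit_table
#' @param hits A tibble in the 12-column layout.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Minimal flatfile reader for fixture records
#'
#' Reads only the fields the pipeline needs from GenBank-style flatfile
#' records: LOCUS name, ORGANISM, /specimen_voucher, and the first
#' REFERENCE title/authors. Intended for small synthetic fixtures, not
#' for real repository dumps.
#'
#' @param path Path to a flatfile with one or more records separated by
#'   `//`.
#' @return A tibble: `accession`, `organism`, `voucher`, `ref_authors`,
#'   `ref_title`, `length`.
#' @export
read_flatfile_minimal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(dplyr::lag(lines == "//", default = FALSE)))
  purrr::map_dfr(recs, function(r) {
    r <- r[r != "//"]
    if (!length(r)) return(NULL)
    g1 <- function(pat) {
      m <- stringr::str_match(r, pat)[, 2]
      m[!is.na(m)][1] %||% NA_character_
    }
    tibble::tibble(
      accession = g1("^LOCUS\\s+(\\S+)"),
      organism = g1("^\\s*ORGANISM\\s+(.*)$"),
      voucher = g1("/specimen_voucher=\"([^\"]*)\""),
      ref_authors = g1("^\\s*AUTHORS\\s+(.*)$"),
      ref_title = g1("^\\s*TITLE\\s+(.*)$"),
      length = as.integer(g1("^LOCUS\\s+\\S+\\s+(\\d+)"))
    )
  })
}
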