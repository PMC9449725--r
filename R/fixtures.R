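# Deterministic synthetic data with planted ground truth. The generator
# emulates the shape of repository-mined inputs (taxonomy with synonyms
# and a monotypic family, multi-locus accession records with vouchers and
# publications, all-by-all similarity hits, gene trees, fossil
# calibrations) so every pipeline stage is testable offline.

BASES <- c("A", "C", "G", "T")

random_seq <- function(len) paste(sample(BASES, len, replace = TRUE),
                                  collapse = "")

# Jukes-Cantor-style site-independent substitution along one branch:
# each site substitutes with p = 3/4 (1 - exp(-4/3 d)), to a uniformly
# chosen different base. No indels.
mutate_seq <- function(seq, d) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- 0.75 * (1 - exp(-4 / 3 * d))
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit) > 0L) {
    shift <- sample(1:3, length(hit), replace = TRUE)
    old <- match(chars[hit], BASES)
    chars[hit] <- BASES[((old - 1L + shift) %% 4L) + 1L]
  }
  paste(chars, collapse = "")
}

#' Simulate sequences down a tree
#'
#' Site-independent substitution (Jukes-Cantor style), branch lengths in
#' expected substitutions per site times `rate`. No indels.
#'
#' @param tree A `phylo` with branch lengths.
#' @param len Sequence length.
#' @param rate Per-locus rate multiplier.
#' @return Named character vector of tip sequences.
#' @export
sim_seqs_on_tree <- function(tree, len, rate = 1) {
  tree <- stats::reorder(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  seqs <- vector("character", n_tip + tree$Nnode)
  seqs[n_tip + 1L] <- random_seq(len)
  for (i in seq_len(nrow(tree$edge))) {
    seqs[tree$edge[i, 2]] <- mutate_seq(seqs[tree$edge[i, 1]],
                                        tree$edge.length[i] * rate)
  }
  stats::setNames(seqs[seq_len(n_tip)], tree$tip.label)
}

# ---- newick assembly --------------------------------------------------------
# Fragments carry no trailing branch length; combining appends one.

# pectinate join of fragments, each child edge of length bl
nwk_join <- function(frags, bl) {
  if (length(frags) == 1L) return(frags)
  sprintf("(%s:%g,%s:%g)", frags[1], bl, nwk_join(frags[-1], bl), bl)
}

# ladder over parts that already carry their branch lengths
nwk_ladder_parts <- function(parts, bl = 0.05) {
  if (length(parts) == 1L) return(parts)
  sprintf("(%s,%s):%g", parts[1], nwk_ladder_parts(parts[-1], bl), bl)
}

default_fixture_loci <- function(n_loci) {
  loci <- c("rbcL", "atpB", "matK", "trnL-trnF", "atpA", "rps4", "rps4-trnS")
  lens <- c(700, 600, 500, 400, 500, 450, 350)
  if (n_loci > length(loci)) stop("at most ", length(loci), " loci",
                                  call. = FALSE)
  tibble::tibble(locus = loci[seq_len(n_loci)], len = lens[seq_len(n_loci)],
                 rate = seq(1, by = 0.2, length.out = n_loci))
}

# assemble the ingroup from per-family fragments (no trailing lengths);
# families 1-2 form a short-stemmed cherry when the order analogs exist
assemble_ingroup <- function(fam_frags, mono_frag, has_analogs) {
  parts <- character()
  ks <- as.integer(names(fam_frags))
  if (has_analogs && all(c(1L, 2L) %in% ks)) {
    parts <- c(parts, sprintf("(%s:0.04,%s:0.04):0.21",
                              fam_frags[["1"]], fam_frags[["2"]]))
    ks <- setdiff(ks, c(1L, 2L))
  }
  for (k in sort(ks)) {
    parts <- c(parts, paste0(fam_frags[[as.character(k)]], ":0.25"))
  }
  if (!is.null(mono_frag)) parts <- c(parts, paste0(mono_frag, ":0.30"))
  nwk_ladder_parts(parts)
}

# literal transcription of the concatenation conditions and selection
# rules, used to fill the manifest (kept deliberately separate from the
# sampling module's implementation)
manifest_select <- function(records, mono_map) {
  len_of <- function(s) sum(!strsplit(toupper(s), "")[[1]] %in% c("?", "N", "-"))
  out <- list()
  for (sp in sort(unique(records$species_id))) {
    rows <- records[records$species_id == sp, ]
    rows$len <- vapply(rows$seq, len_of, integer(1))
    cands <- list()
    push <- function(rws, basis) {
      pick <- do.call(rbind, lapply(split(rws, rws$locus), function(x) {
        x[order(-x$len, x$accession), ][1, ]
      }))
      cands[[length(cands) + 1L]] <<- list(
        basis = basis, locus = pick$locus, accession = pick$accession,
        total = sum(pick$len),
        rbcL_len = sum(pick$len[pick$locus == "rbcL"]),
        has_rbcL = "rbcL" %in% pick$locus, n_loci = nrow(pick))
    }
    if (isTRUE(mono_map[sp] %||% TRUE)) push(rows, "monophyly")
    for (v in sort(unique(rows$voucher[!is.na(rows$voucher)]))) {
      vr <- rows[!is.na(rows$voucher) & rows$voucher == v, ]
      if (nrow(vr) >= 2L) push(vr, "voucher")
    }
    if (nrow(rows) >= 2L && !anyNA(rows$publication) &&
        length(unique(rows$publication)) == 1L) push(rows, "publication")
    for (i in seq_len(nrow(rows))) push(rows[i, ], "single")

    key <- function(c_, primary) {
      sprintf("%012.0f|%012.0f|%04d|%s", 10^9 - primary, 10^9 - c_$total,
              9999 - c_$n_loci, paste(sort(c_$accession), collapse = "|"))
    }
    s1 <- Filter(function(c_) c_$has_rbcL && c_$n_loci >= 2L, cands)
    if (length(s1) > 0L) {
      pick <- s1[[order(vapply(s1, function(c_) key(c_, c_$total),
                               character(1)))[1]]]
      rule <- "S1"
    } else {
      s2 <- Filter(function(c_) c_$has_rbcL, cands)
      if (length(s2) > 0L) {
        pick <- s2[[order(vapply(s2, function(c_) key(c_, c_$rbcL_len),
                                 character(1)))[1]]]
        rule <- "S2"
      } else {
        pick <- cands[[order(vapply(cands, function(c_) key(c_, c_$total),
                                    character(1)))[1]]]
        rule <- "S3"
      }
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      species_id = sp, rule = rule,
      members = list(stats::setNames(pick$accession, pick$locus)))
  }
  dplyr::bind_rows(out)
}

#' Generate a synthetic input bundle with planted ground truth
#'
#' Builds, purely as a function of `seed` and the size parameters, a
#' complete toy input set: a Darwin Core taxonomy (one genus per family,
#' planted synonyms, a monotypic family, and — when `n_families >= 3` —
#' a Cyatheales order analog of two closely related families plus a
#' Saccolomatineae suborder holding the third family), a species tree
#' with an algal outgroup, per-locus accession-labelled gene trees,
#' multi-locus Sanger records with voucher/publication structure (plus a
#' small plastome tier and three inadmissible records), planted rogues
#' (sequences copied across families, each from a distinct donor
#' species), an all-by-all similarity table scored with the package's
#' local aligner, synthetic fossil calibrations (including a redundant
#' pair and one with missing anchors), and a manifest of expected
#' outputs derived from the planted truth and a literal transcription of
#' the selection rules.
#'
#' @param seed Integer seed; the bundle is a pure function of the
#'   arguments.
#' @param n_families Number of regular families (1-26; >= 3 enables the
#'   rank-override analogs).
#' @param n_species_per_family Species per family (1-26; >= 4 exercises
#'   every concatenation condition and the planted non-monophyly).
#' @param n_loci Number of loci (1-7; the first is rbcL, the fourth the
#'   trnL-trnF spacer).
#' @param rogue_rate Fraction (0 <= r < 1) of candidate accessions turned
#'   into planted rogues.
#' @return A list of class `fixture_bundle` with elements `taxonomy`,
#'   `records`, `inadmissible`, `plastome_records`, `hits`, `gene_trees`,
#'   `species_tree`, `outgroup`, `calibrations`, `spacer_alignment`, and
#'   `manifest` (expected rogues, resolution, representatives, plastome
#'   picks, surviving calibrations, trim columns).
#' @export
make_toy_dataset <- function(seed, n_families = 5, n_species_per_family = 4,
                             n_loci = 4, rogue_rate = 0.1) {
  stopifnot(n_families >= 1, n_species_per_family >= 1, n_loci >= 1,
            rogue_rate >= 0, rogue_rate < 1)
  if (n_families > 26 || n_species_per_family > 26) {
    stop("degenerate sizes: at most 26 families and species per family",
         call. = FALSE)
  }
  set.seed(seed)
  loci <- default_fixture_loci(n_loci)
  has_analogs <- n_families >= 3

  fam_name <- function(k) paste0("Fam", letters[k], "aceae")
  gen_name <- function(k) paste0("Gen", letters[k], "ium")
  sp_name <- function(k, j) paste(gen_name(k), paste0(letters[j], "ense"))
  sp_id <- function(k, j) sprintf("sp_%02d_%02d", k, j)

  # ---- taxonomy -------------------------------------------------------------
  rows <- list()
  add <- function(id, name, auth, rank, status, acc, par) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      taxon_id = id, scientific_name = name, authorship = auth, rank = rank,
      status = status, accepted_id = acc, parent_id = par)
  }
  add("ord_poly", "Polypodiales", "", "order", "accepted", NA, NA)
  if (has_analogs) {
    add("ord_cya", "Cyatheales", "", "order", "accepted", NA, NA)
    add("sub_sac", "Saccolomatineae", "", "suborder", "accepted", NA, "ord_poly")
  }
  fam_parent <- function(k) {
    if (!has_analogs) return("ord_poly")
    if (k <= 2) "ord_cya" else if (k == 3) "sub_sac" else "ord_poly"
  }
  for (k in seq_len(n_families)) {
    add(sprintf("fam_%02d", k), fam_name(k), "", "family", "accepted",
        NA, fam_parent(k))
    add(sprintf("gen_%02d", k), gen_name(k), "", "genus", "accepted",
        NA, sprintf("fam_%02d", k))
    for (j in seq_len(n_species_per_family)) {
      add(sp_id(k, j), sp_name(k, j), "Sm.", "species", "accepted",
          NA, sprintf("gen_%02d", k))
    }
    add(sprintf("syn_%02d", k), paste(paste0("Palaeogen", letters[k], "ium"),
                                      "aense"),
        "(L.) Sm.", "species", "synonym", sp_id(k, 1), NA)
  }
  add("fam_mono", "Monotypicaceae", "", "family", "accepted", NA, "ord_poly")
  add("gen_mono", "Monogenium", "", "genus", "accepted", NA, "fam_mono")
  add("sp_mono", "Monogenium solum", "Sm.", "species", "accepted", NA, "gen_mono")
  add("ord_alg", "Algales", "", "order", "accepted", NA, NA)
  add("fam_alg", "Algaceae", "", "family", "accepted", NA, "ord_alg")
  add("gen_alg", "Algagenium", "", "genus", "accepted", NA, "fam_alg")
  add("sp_out", "Algagenium primum", "Sm.", "species", "accepted", NA, "gen_alg")
  taxonomy <- dplyr::bind_rows(rows)

  # ---- species tree ---------------------------------------------------------
  fam_frag <- function(k) {
    ids <- vapply(seq_len(n_species_per_family), function(j) sp_id(k, j),
                  character(1))
    nwk_join(ids, 0.02)
  }
  fam_frags <- stats::setNames(
    lapply(seq_len(n_families), fam_frag), as.character(seq_len(n_families)))
  ingroup <- assemble_ingroup(fam_frags, "sp_mono", has_analogs)
  species_tree <- ape::read.tree(
    text = sprintf("(%s:0.10,sp_out:0.80);", ingroup))

  # ---- accession plan -------------------------------------------------------
  acc_id <- function(k, j, locus, copy)
    sprintf("A%02d%02d%s%d", k, j, gsub("[^A-Za-z0-9]", "", locus), copy)
  recs <- list()
  addrec <- function(k, j, locus, copy, voucher = NA, publication = NA) {
    recs[[length(recs) + 1L]] <<- tibble::tibble(
      accession = acc_id(k, j, locus, copy), locus = locus,
      species_id = sp_id(k, j), raw_name = sp_name(k, j),
      voucher = voucher, publication = publication, tier = "sanger",
      copy = copy)
  }
  for (k in seq_len(n_families)) {
    for (j in seq_len(n_species_per_family)) {
      scen <- ((j - 1L) %% 4L) + 1L
      if (scen == 1L) {
        v <- sprintf("Smith %d%02d", k, j)
        addrec(k, j, "rbcL", 1, voucher = v)
        addrec(k, j, "rbcL", 2, voucher = v)
        if (n_loci >= 2) addrec(k, j, loci$locus[2], 1, voucher = v)
      } else if (scen == 2L) {
        p <- sprintf("auth%02d_2001_1", k)
        addrec(k, j, "rbcL", 1, publication = p)
        if (n_loci >= 3) addrec(k, j, loci$locus[3], 1, publication = p)
        if (n_loci >= 4) addrec(k, j, loci$locus[4], 1, publication = p)
      } else if (scen == 3L) {
        addrec(k, j, "rbcL", 1, voucher = sprintf("Jones %d%02da", k, j),
               publication = sprintf("pubA%02d%02d", k, j))
        addrec(k, j, "rbcL", 2, voucher = sprintf("Jones %d%02db", k, j),
               publication = sprintf("pubB%02d%02d", k, j))
        if (n_loci >= 2) addrec(k, j, loci$locus[2], 1)
      } else {
        for (l in seq_len(n_loci)) addrec(k, j, loci$locus[l], 1,
          publication = sprintf("pubC%02d%02d%d", k, j, l))
      }
    }
  }
  recs[[length(recs) + 1L]] <- tibble::tibble(
    accession = "AMONOrbcL1", locus = "rbcL", species_id = "sp_mono",
    raw_name = "Monogenium solum", voucher = NA, publication = NA,
    tier = "sanger", copy = 1)
  records <- dplyr::bind_rows(recs)

  # planted name-resolution challenges: one synonym usage, one misspelling
  syn_rec <- which(records$species_id == sp_id(1, 1))[1]
  records$raw_name[syn_rec] <- taxonomy$scientific_name[
    taxonomy$taxon_id == "syn_01"]
  if (n_families >= 2 && n_species_per_family >= 2) {
    mis_rec <- which(records$species_id == sp_id(2, 2))[1]
    nm <- records$raw_name[mis_rec]
    substr(nm, nchar(nm), nchar(nm)) <- "a"  # "...ense" -> "...ensa"
    records$raw_name[mis_rec] <- nm
  }
  expected_resolution <- stats::setNames(records$species_id,
                                         records$accession)

  # inadmissible extras (dropped before anything downstream)
  inadmissible <- tibble::tibble(
    accession = c("ABAD1", "ABAD2", "ABAD3"),
    locus = "rbcL",
    species_id = NA_character_,
    raw_name = c(paste0(gen_name(1), " cf. aense"),
                 paste(sp_name(1, 1), "×", sp_name(1, 2)),
                 "uncultured fern clone 7"),
    voucher = NA_character_, publication = NA_character_, tier = "sanger")

  # ---- sequences ------------------------------------------------------------
  seqs_by_locus <- lapply(seq_len(n_loci), function(l) {
    sim_seqs_on_tree(species_tree, loci$len[l], loci$rate[l])
  })
  names(seqs_by_locus) <- loci$locus
  records$seq <- vapply(seq_len(nrow(records)), function(i) {
    base <- seqs_by_locus[[records$locus[i]]][[records$species_id[i]]]
    if (records$copy[i] >= 2L) {
      s <- mutate_seq(base, 0.004)
      # second copies carry a short run of Ns so lengths differ
      substr(s, 11L, 20L) <- strrep("N", 10L)
      s
    } else base
  }, character(1))
  inadmissible$seq <- substr(records$seq[1], 1, 200)
  records$copy <- NULL

  # ---- planted rogues -------------------------------------------------------
  # Each rogue's sequence is replaced by a lightly mutated copy of a
  # donor species from a family differing at the query's comparison
  # rank; donors are distinct (family, species) pairs so that no clean
  # query can accumulate three near-identical foreign neighbours.
  rank_group <- function(k) if (has_analogs && k <= 2) "CYA" else paste0("F", k)
  j_last <- n_species_per_family
  rogue_candidates <- vapply(seq_len(n_families),
                             function(k) acc_id(k, j_last, "rbcL", 1),
                             character(1))
  rogue_candidates <- rogue_candidates[rogue_candidates %in% records$accession]
  n_rogues <- if (rogue_rate > 0 && n_families >= 2) {
    min(length(rogue_candidates),
        max(1L, ceiling(rogue_rate * length(rogue_candidates))))
  } else 0L
  planted_rogues <- character()
  if (n_rogues > 0L) {
    planted_rogues <- sort(sample(rogue_candidates, n_rogues))
    used_donors <- list()
    donor_family <- function(k) {
      for (d in (seq(k, length.out = n_families - 1L) %% n_families) + 1L) {
        if (rank_group(d) != rank_group(k)) return(d)
      }
      stop("no donor family available", call. = FALSE)
    }
    for (acc in planted_rogues) {
      k <- as.integer(substr(acc, 2, 3))
      d <- donor_family(k)
      js <- c(seq(2L, length.out = max(0L, n_species_per_family - 1L)), 1L)
      dj <- js[1]
      for (j in js) {
        if (!paste(d, j) %in% used_donors) { dj <- j; break }
      }
      used_donors[[length(used_donors) + 1L]] <- paste(d, dj)
      donor_seq <- seqs_by_locus[["rbcL"]][[sp_id(d, dj)]]
      records$seq[records$accession == acc] <- mutate_seq(donor_seq, 0.01)
    }
    # the monotypic family's sequence is foreign too: it would be flagged
    # but is exempt, exercising the exemption
    donor_seq <- seqs_by_locus[["rbcL"]][[sp_id(1, 1)]]
    records$seq[records$accession == "AMONOrbcL1"] <-
      mutate_seq(donor_seq, 0.01)
  }

  # ---- all-by-all hit table -------------------------------------------------
  hits <- fixture_hit_table(records)

  # ---- gene trees (post rogue removal, accession-labelled) ------------------
  clean_records <- records[!records$accession %in% planted_rogues, ]
  nonmono_species <- if (n_species_per_family >= 4) sp_id(1, 3) else NULL
  gene_trees <- list()
  for (lc in loci$locus) {
    tr <- fixture_gene_tree(clean_records, lc, n_families,
                            n_species_per_family, sp_id, has_analogs,
                            nonmono_species)
    if (!is.null(tr)) gene_trees[[lc]] <- tr
  }

  # ---- plastome tier --------------------------------------------------------
  plast <- list()
  if (n_families >= 4 && n_species_per_family >= 2) {
    for (j in 1:2) {
      for (spec in 1:2) {
        n_here <- if (spec == 1L) n_loci else max(1L, n_loci - 1L)
        for (l in seq_len(n_here)) {
          plast[[length(plast) + 1L]] <- tibble::tibble(
            accession = sprintf("P%02d%02d_%d_%s", 4L, j, spec,
                                gsub("[^A-Za-z0-9]", "", loci$locus[l])),
            specimen = sprintf("P%02d%02d_%d", 4L, j, spec),
            species_id = sp_id(4, j), locus = loci$locus[l],
            seq = seqs_by_locus[[loci$locus[l]]][[sp_id(4, j)]],
            tier = "plastome")
        }
      }
    }
  }
  plastome_records <- if (length(plast) > 0L) dplyr::bind_rows(plast) else
    tibble::tibble(accession = character(), specimen = character(),
                   species_id = character(), locus = character(),
                   seq = character(), tier = character())

  # ---- spacer alignment with planted gappy columns --------------------------
  spacer_alignment <- NULL
  expected_trim <- NULL
  if ("trnL-trnF" %in% loci$locus) {
    sp_ids <- setdiff(taxonomy$taxon_id[taxonomy$rank == "species" &
                                          taxonomy$status == "accepted"],
                      "sp_out")
    seqs <- seqs_by_locus[["trnL-trnF"]][sp_ids]
    m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
    m[1, 5] <- "-"                                 # rare gap column
    m[seq_len(ceiling(nrow(m) / 2)), 10] <- "-"    # common gap column
    spacer_alignment <- locus_alignment(
      stats::setNames(apply(m, 1, paste, collapse = ""), sp_ids), "trnL-trnF")
    gf <- colMeans(m == "-")
    expected_trim <- list(at_0.05 = which(gf > 0.05),
                          at_0.01 = which(gf > 0.01))
  }

  # ---- fossil calibrations (synthetic) --------------------------------------
  cal <- list()
  addcal <- function(id, clade, placement, a1, a2, age) {
    cal[[length(cal) + 1L]] <<- tibble::tibble(
      id = id, fossil_name = paste0("Fossilites ", id),
      clade_name = clade, placement = placement, anchor1 = a1, anchor2 = a2,
      min_age = age, period = "Synthetic", citation = "synthetic fixture")
  }
  if (n_species_per_family >= 2) {
    for (k in seq_len(min(3L, n_families))) {
      addcal(sprintf("cal_crown_%02d", k), fam_name(k), "crown",
             sp_id(k, 1), sp_id(k, n_species_per_family), 40 + 10 * k)
    }
    if (n_families >= 2) {
      # redundant with cal_crown_02 (same crown node), older -> wins
      addcal("cal_dup_old", fam_name(2), "crown", sp_id(2, 1),
             sp_id(2, n_species_per_family), 95)
      addcal("cal_stem_01", fam_name(1), "stem", sp_id(1, 1),
             sp_id(1, n_species_per_family), 120)
    }
  }
  addcal("cal_missing", "Ghostaceae", "crown", "sp_99_01", "sp_99_02", 77)
  calibrations <- dplyr::bind_rows(cal)

  # ---- manifest -------------------------------------------------------------
  mono_map <- stats::setNames(
    rep(TRUE, length(unique(clean_records$species_id))),
    sort(unique(clean_records$species_id)))
  if (!is.null(nonmono_species) && nonmono_species %in% names(mono_map)) {
    mono_map[nonmono_species] <- FALSE
  }
  plastome_species <- unique(plastome_records$species_id)
  sanger_input <- clean_records[!clean_records$species_id %in%
                                  plastome_species, ]
  expected_repr <- manifest_select(sanger_input, mono_map)
  expected_plastome <- if (nrow(plastome_records) > 0L) {
    purrr::map_dfr(sort(unique(plastome_records$species_id)), function(sp) {
      rows <- plastome_records[plastome_records$species_id == sp, ]
      tot <- tapply(ungapped_length(rows$seq), rows$specimen, sum)
      best <- names(tot)[order(-tot, names(tot))][1]
      tibble::tibble(species_id = sp, specimen = best)
    })
  } else tibble::tibble(species_id = character(), specimen = character())

  manifest <- list(
    expected_rogues = planted_rogues,
    expected_exempt = if (n_rogues > 0L) "AMONOrbcL1" else character(),
    expected_nonmonophyletic = nonmono_species %||% character(),
    expected_resolution = expected_resolution,
    expected_monophyly = mono_map,
    expected_representatives = expected_repr,
    expected_plastome = expected_plastome,
    expected_calibration_kept = fixture_expected_calibrations(
      species_tree, calibrations),
    expected_trim = expected_trim
  )

  structure(list(
    seed = seed, loci = loci, taxonomy = taxonomy,
    records = records, inadmissible = inadmissible,
    plastome_records = plastome_records,
    hits = hits, gene_trees = gene_trees, species_tree = species_tree,
    outgroup = "sp_out",
    calibrations = calibrations, spacer_alignment = spacer_alignment,
    manifest = manifest
  ), class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle> seed ", x$seed, ": ",
      sum(x$taxonomy$rank == "species" & x$taxonomy$status == "accepted"),
      " species, ", nrow(x$records), " Sanger records, ",
      nrow(x$hits), " hits, ", length(x$gene_trees), " gene trees, ",
      length(x$manifest$expected_rogues), " planted rogues\n", sep = "")
  invisible(x)
}

# all-by-all similarity table per locus, scored with the package aligner
fixture_hit_table <- function(records) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  out <- list()
  for (lc in unique(records$locus)) {
    rows <- records[records$locus == lc, ]
    ss <- Biostrings::DNAStringSet(gsub("[?N-]", "A", rows$seq))
    names(ss) <- rows$accession
    for (i in seq_len(nrow(rows))) {
      al <- Biostrings::pairwiseAlignment(
        pattern = ss, subject = ss[[i]], type = "local",
        substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
      sc <- Biostrings::score(al)
      w <- Biostrings::nchar(al)
      out[[length(out) + 1L]] <- tibble::tibble(
        qseqid = rows$accession, sseqid = rows$accession[i],
        pident = Biostrings::pid(al), length = w,
        mismatch = 0L, gapopen = 0L, qstart = 1L, qend = w,
        sstart = 1L, send = w, evalue = 2^(-sc / 10), bitscore = sc)
    }
  }
  dplyr::bind_rows(out)
}

# accession-labelled gene tree for one locus; optionally plants one
# non-monophyletic species by grafting its second accession next to the
# second species of family 1
fixture_gene_tree <- function(records, locus, n_families,
                              n_species_per_family, sp_id, has_analogs,
                              nonmono_species) {
  rows <- records[records$locus == locus, ]
  if (nrow(rows) < 3L) return(NULL)
  unit <- function(k, j) {
    accs <- sort(rows$accession[rows$species_id == sp_id(k, j)])
    if (length(accs) == 0L) return(NULL)
    if (length(accs) == 1L) return(accs)
    nwk_join(accs, 0.005)
  }
  fam_frags <- list()
  for (k in seq_len(n_families)) {
    units <- list()
    for (j in seq_len(n_species_per_family)) {
      u <- unit(k, j)
      if (!is.null(u)) units[[as.character(j)]] <- u
    }
    if (!is.null(nonmono_species) && locus == "rbcL" && k == 1L) {
      accs3 <- sort(rows$accession[rows$species_id == nonmono_species])
      if (length(accs3) >= 2L && !is.null(units[["2"]])) {
        units[["3"]] <- nwk_join(accs3[-2], 0.005)
        units[["2"]] <- sprintf("(%s:0.005,%s:0.005)", accs3[2],
                                units[["2"]])
      }
    }
    if (length(units) > 0L) {
      fam_frags[[as.character(k)]] <- nwk_join(unlist(units), 0.02)
    }
  }
  mono_accs <- sort(rows$accession[rows$species_id == "sp_mono"])
  mono_frag <- if (length(mono_accs) >= 1L) nwk_join(mono_accs, 0.005) else NULL
  if (length(fam_frags) == 0L) return(NULL)
  ingroup <- assemble_ingroup(fam_frags, mono_frag, has_analogs)
  tr <- ape::collapse.singles(ape::read.tree(text = paste0("(", ingroup, ");")))
  if (length(tr$tip.label) < 3L) return(NULL)
  ape::unroot(tr)
}

# expected surviving calibration ids: bind anchors to nodes, per node
# keep the oldest (ties by id)
fixture_expected_calibrations <- function(species_tree, calibrations) {
  tr <- species_tree
  n_tip <- length(tr$tip.label)
  nodes <- vapply(seq_len(nrow(calibrations)), function(i) {
    cl <- calibrations[i, ]
    anch <- intersect(c(cl$anchor1, cl$anchor2), tr$tip.label)
    if (cl$placement == "crown" && length(anch) < 2L) return(NA_integer_)
    if (length(anch) == 0L) return(NA_integer_)
    crown <- if (length(anch) >= 2L) ape::getMRCA(tr, anch) else
      tr$edge[tr$edge[, 2] == which(tr$tip.label == anch), 1]
    if (cl$placement == "stem") {
      if (crown == n_tip + 1L) return(NA_integer_)
      if (length(anch) >= 2L) crown <- tr$edge[tr$edge[, 2] == crown, 1]
    }
    as.integer(crown)
  }, integer(1))
  keep <- character()
  for (nd in sort(unique(stats::na.omit(nodes)))) {
    idx <- which(!is.na(nodes) & nodes == nd)
    ord <- idx[order(-calibrations$min_age[idx], calibrations$id[idx])]
    keep <- c(keep, calibrations$id[ord[1]])
  }
  sort(keep)
}
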