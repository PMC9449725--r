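# Independent oracles used across tests: plain transcriptions of the
# rules and brute-force algorithms, deliberately written without reusing
# the package's implementation paths.

# classic dynamic-programming Levenshtein distance
oracle_lev <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  prev <- 0:length(cb)
  for (i in seq_along(ca)) {
    cur <- c(i, rep(0L, length(cb)))
    for (j in seq_along(cb)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (ca[i] != cb[j]))
    }
    prev <- cur
  }
  prev[length(cb) + 1]
}

# full Smith-Waterman (match +1, mismatch -1, linear gap -2); returns the
# best score and the 0-based half-open span of the best alignment on a
oracle_sw <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  H <- matrix(0, n + 1, m + 1)
  best <- 0; best_i <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (ca[i] == cb[j]) 1 else -1
      H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] - 2, H[i + 1, j] - 2)
      if (H[i + 1, j + 1] > best) { best <- H[i + 1, j + 1]; best_i <- i }
    }
  }
  # traceback for the start row of the best cell
  bj <- which.max(H[best_i + 1, ]) - 1
  i <- best_i; j <- bj
  while (H[i + 1, j + 1] > 0) {
    s <- if (ca[i] == cb[j]) 1 else -1
    if (i > 0 && j > 0 && H[i + 1, j + 1] == H[i, j] + s) { i <- i - 1; j <- j - 1 }
    else if (H[i + 1, j + 1] == H[i, j + 1] - 2) i <- i - 1
    else j <- j - 1
  }
  list(score = best, q_start = i, q_end = best_i)
}

# all bipartitions of an unrooted tree (and all clades of a rooted one),
# found by removing each edge and flooding the tip sets on either side --
# no ape clade machinery
oracle_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  edges <- tree$edge
  sets <- list()
  for (r in seq_len(nrow(edges))) {
    # flood from the child side over all edges except the removed one
    seen <- edges[r, 2]
    repeat {
      added <- FALSE
      for (rr in seq_len(nrow(edges))) {
        if (rr == r) next
        a <- edges[rr, 1]; b <- edges[rr, 2]
        if (a %in% seen && !b %in% seen) { seen <- c(seen, b); added <- TRUE }
        if (b %in% seen && !a %in% seen) { seen <- c(seen, a); added <- TRUE }
      }
      if (!added) break
    }
    sets[[r]] <- sort(tree$tip.label[seen[seen <= n_tip]])
  }
  unique(sets)
}

# is `tips` a split of the unrooted tree / clade of the rooted tree?
oracle_is_mono <- function(tree, tips) {
  tips <- sort(tips)
  if (length(tips) <= 1L) return(TRUE)
  if (length(tips) == length(tree$tip.label)) return(TRUE)
  sets <- oracle_tip_sets(tree)
  rooted <- ape::is.rooted(tree)
  for (s in sets) {
    comp <- sort(setdiff(tree$tip.label, s))
    if (identical(s, tips)) return(TRUE)
    if (!rooted && identical(comp, tips)) return(TRUE)
  }
  FALSE
}

# literal transcription of the rogue rule: top three distinct subjects by
# (score desc, evalue asc, id asc) after dropping self-hits; flagged iff
# all three differ from the query at the comparison rank; monotypic
# families exempt; < 3 usable hits indeterminate
oracle_rogues <- function(hits, acc2species, lineages, overrides) {
  res <- list()
  for (q in sort(unique(hits$qseqid))) {
    if (!q %in% names(acc2species)) next
    ql <- lineages[lineages$species_id == acc2species[[q]], ]
    rank <- "family"
    if (ql$order %in% overrides$taxon) {
      rank <- overrides$rank[overrides$taxon == ql$order]
    } else if (!is.na(ql$suborder) && ql$suborder %in% overrides$taxon) {
      rank <- overrides$rank[overrides$taxon == ql$suborder]
    }
    pick_taxon <- function(l) {
      v <- switch(rank, family = l$family, order = l$order,
                  suborder = l$suborder)
      if (length(v) == 0) NA_character_ else v
    }
    h <- hits[hits$qseqid == q & hits$sseqid != q &
                hits$sseqid %in% names(acc2species), ]
    h <- h[order(-h$bitscore, h$evalue, h$sseqid), ]
    subjects <- unique(h$sseqid)[seq_len(min(3, length(unique(h$sseqid))))]
    status <- if (isTRUE(ql$is_monotypic_family)) "exempt_monotypic"
      else if (length(subjects) < 3) "indeterminate"
      else {
        taxa <- vapply(subjects, function(s)
          pick_taxon(lineages[lineages$species_id == acc2species[[s]], ]),
          character(1))
        if (all(is.na(taxa) | taxa != pick_taxon(ql))) "rogue" else "clean"
      }
    res[[q]] <- status
  }
  unlist(res)
}

# literal transcription of the concatenation conditions (1-3 plus
# unconcatenated singles) and the selection rules S1-S3, with the
# documented tie-break (greater total, more loci, accession tuple)
oracle_selection <- function(records, mono) {
  ulen <- function(s) sum(!strsplit(toupper(s), "")[[1]] %in% c("?", "N", "-"))
  res <- list()
  for (sp in sort(unique(records$species_id))) {
    rws <- records[records$species_id == sp, ]
    rws$len <- vapply(rws$seq, ulen, integer(1))
    longest <- function(d) {
      out <- NULL
      for (lc in sort(unique(d$locus))) {
        x <- d[d$locus == lc, ]
        x <- x[order(-x$len, x$accession), ][1, ]
        out <- rbind(out, x)
      }
      out
    }
    cands <- list()
    if (isTRUE(mono[sp]) || !sp %in% names(mono)) {
      cands[[length(cands) + 1]] <- longest(rws)
    }
    if (!is.null(rws$voucher)) {
      for (v in sort(unique(rws$voucher[!is.na(rws$voucher)]))) {
        d <- rws[!is.na(rws$voucher) & rws$voucher == v, ]
        if (nrow(d) >= 2) cands[[length(cands) + 1]] <- longest(d)
      }
    }
    if (!is.null(rws$publication) && nrow(rws) >= 2 &&
        !anyNA(rws$publication) && length(unique(rws$publication)) == 1) {
      cands[[length(cands) + 1]] <- longest(rws)
    }
    for (i in seq_len(nrow(rws))) cands[[length(cands) + 1]] <- rws[i, ]

    stat <- lapply(cands, function(d) list(
      total = sum(d$len), n = nrow(d),
      rbcl = sum(d$len[d$locus == "rbcL"]),
      has_rbcl = "rbcL" %in% d$locus,
      accs = paste(sort(d$accession), collapse = "|")))
    better <- function(i, j, key) {
      a <- stat[[i]]; b <- stat[[j]]
      ka <- c(key(a), a$total, a$n); kb <- c(key(b), b$total, b$n)
      for (z in 1:3) {
        if (ka[z] > kb[z]) return(TRUE)
        if (ka[z] < kb[z]) return(FALSE)
      }
      a$accs < b$accs
    }
    argbest <- function(idx, key) {
      b <- idx[1]
      for (i in idx[-1]) if (better(i, b, key)) b <- i
      b
    }
    i_s1 <- which(vapply(stat, function(s) s$has_rbcl && s$n >= 2, logical(1)))
    i_s2 <- which(vapply(stat, function(s) s$has_rbcl, logical(1)))
    if (length(i_s1) > 0) {
      pick <- argbest(i_s1, function(s) s$total); rule <- "S1"
    } else if (length(i_s2) > 0) {
      pick <- argbest(i_s2, function(s) s$rbcl); rule <- "S2"
    } else {
      pick <- argbest(seq_along(stat), function(s) s$total); rule <- "S3"
    }
    d <- cands[[pick]]
    res[[sp]] <- list(rule = rule,
                      members = stats::setNames(d$accession, d$locus))
  }
  res
}

# small taxonomy used across qc tests: two orders, a suborder analog, a
# monotypic family
make_test_taxonomy <- function(n_plain_families = 2,
                               n_species = 3) {
  rows <- list(
    c("ord_cya", "Cyatheales", "order", "accepted", NA, NA),
    c("ord_pol", "Polypodiales", "order", "accepted", NA, NA),
    c("sub_sac", "Saccolomatineae", "suborder", "accepted", NA, "ord_pol"),
    c("fam_c1", "Cyatheaceae", "family", "accepted", NA, "ord_cya"),
    c("fam_c2", "Plagiogyriaceae", "family", "accepted", NA, "ord_cya"),
    c("fam_s1", "Saccolomataceae", "family", "accepted", NA, "sub_sac"),
    c("fam_m", "Monacheae", "family", "accepted", NA, "ord_pol")
  )
  for (k in seq_len(n_plain_families)) {
    rows[[length(rows) + 1]] <- c(paste0("fam_p", k),
                                  paste0("Plainfam", k, "aceae"),
                                  "family", "accepted", NA, "ord_pol")
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("taxon_id", "scientific_name", "rank", "status",
                 "accepted_id", "parent_id")
  fams <- df$taxon_id[df$rank == "family"]
  out <- df
  for (f in fams) {
    g <- sub("fam", "gen", f)
    out <- rbind(out, c(g, paste0("Genus", f), "genus", "accepted", NA, f))
    n_sp <- if (f == "fam_m") 1 else n_species
    for (j in seq_len(n_sp)) {
      out <- rbind(out, c(paste0(f, "_sp", j),
                          paste0("Genus", f, " sp", letters[j]),
                          "species", "accepted", NA, g))
    }
  }
  tb <- tibble::as_tibble(out)
  tb$authorship <- ""
  tb
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
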