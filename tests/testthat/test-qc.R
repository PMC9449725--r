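# hit-table builder: rows of (query, subject, score, evalue)
hit_rows <- function(...) {
  m <- rbind(...)
  tibble::tibble(qseqid = m[, 1], sseqid = m[, 2],
                 bitscore = as.numeric(m[, 3]),
                 evalue = as.numeric(m[, 4]))
}

test_that("the top-three family-mismatch rule fires exactly as specified", {
  tax <- make_test_taxonomy()
  acc2sp <- c(Q1 = "fam_p1_sp1", S1 = "fam_p1_sp2", S2 = "fam_p2_sp1",
              S3 = "fam_p2_sp2", S4 = "fam_p2_sp3")

  # top hit in the query's own family: rule cannot fire
  h <- hit_rows(c("Q1", "S1", 500, 1e-60), c("Q1", "S2", 400, 1e-50),
                c("Q1", "S3", 300, 1e-40), c("Q1", "S4", 200, 1e-30))
  r <- detect_rogues(h, acc2sp, tax)
  expect_equal(r$status[r$accession == "Q1"], "clean")

  # all top-3 subjects in a foreign family: rogue
  h <- hit_rows(c("Q1", "S2", 500, 1e-60), c("Q1", "S3", 400, 1e-50),
                c("Q1", "S4", 300, 1e-40), c("Q1", "S1", 200, 1e-30))
  r <- detect_rogues(h, acc2sp, tax)
  expect_equal(r$status[r$accession == "Q1"], "rogue")
  expect_true(r$flagged[r$accession == "Q1"])

  # self-hits are dropped before ranking
  h <- hit_rows(c("Q1", "Q1", 999, 0), c("Q1", "S2", 500, 1e-60),
                c("Q1", "S3", 400, 1e-50), c("Q1", "S4", 300, 1e-40))
  r <- detect_rogues(h, acc2sp, tax)
  expect_equal(r$status[r$accession == "Q1"], "rogue")

  # fewer than three usable subjects: indeterminate, never flagged
  h <- hit_rows(c("Q1", "S2", 500, 1e-60), c("Q1", "S3", 400, 1e-50))
  r <- detect_rogues(h, acc2sp, tax)
  expect_equal(r$status[r$accession == "Q1"], "indeterminate")
  expect_false(r$flagged[r$accession == "Q1"])

  # multiple rows per subject collapse to that subject's best row
  h <- hit_rows(c("Q1", "S2", 500, 1e-60), c("Q1", "S2", 450, 1e-55),
                c("Q1", "S3", 400, 1e-50), c("Q1", "S2", 350, 1e-45))
  r <- detect_rogues(h, acc2sp, tax)
  expect_equal(r$status[r$accession == "Q1"], "indeterminate")
})

test_that("monotypic families are exempt and rank overrides apply", {
  tax <- make_test_taxonomy()
  acc2sp <- c(QM = "fam_m_sp1", QC = "fam_c1_sp1", QS = "fam_s1_sp1",
              S1 = "fam_c2_sp1", S2 = "fam_c2_sp2", S3 = "fam_c2_sp3",
              P1 = "fam_p1_sp1", P2 = "fam_p1_sp2", P3 = "fam_p1_sp3",
              T1 = "fam_s1_sp2", T2 = "fam_s1_sp3")

  # monotypic-family query with three foreign top hits is exempt
  h <- hit_rows(c("QM", "S1", 500, 1e-60), c("QM", "S2", 400, 1e-50),
                c("QM", "S3", 300, 1e-40))
  r <- detect_rogues(h, acc2sp, tax)
  expect_equal(r$status[r$accession == "QM"], "exempt_monotypic")
  expect_false(r$flagged[r$accession == "QM"])

  # Cyatheales query compared at order level: sister-family hits are clean
  h <- hit_rows(c("QC", "S1", 500, 1e-60), c("QC", "S2", 400, 1e-50),
                c("QC", "S3", 300, 1e-40))
  r <- detect_rogues(h, acc2sp, tax)
  expect_equal(r$comparison_rank[r$accession == "QC"], "order")
  expect_equal(r$status[r$accession == "QC"], "clean")
  # ... but hits outside the order still flag it
  h <- hit_rows(c("QC", "P1", 500, 1e-60), c("QC", "P2", 400, 1e-50),
                c("QC", "P3", 300, 1e-40))
  r <- detect_rogues(h, acc2sp, tax)
  expect_equal(r$status[r$accession == "QC"], "rogue")

  # Saccolomatineae query compared at suborder level
  h <- hit_rows(c("QS", "T1", 500, 1e-60), c("QS", "T2", 400, 1e-50),
                c("QS", "P1", 300, 1e-40))
  r <- detect_rogues(h, acc2sp, tax)
  expect_equal(r$comparison_rank[r$accession == "QS"], "suborder")
  expect_equal(r$status[r$accession == "QS"], "clean")
  h <- hit_rows(c("QS", "P1", 500, 1e-60), c("QS", "P2", 400, 1e-50),
                c("QS", "P3", 300, 1e-40))
  r <- detect_rogues(h, acc2sp, tax)
  expect_equal(r$status[r$accession == "QS"], "rogue")
})

test_that("rogue detection is invariant to input row order", {
  tax <- make_test_taxonomy()
  set.seed(11)
  acc <- c(paste0("A", 1:4), paste0("B", 1:4), paste0("C", 1:4))
  acc2sp <- stats::setNames(
    c(paste0("fam_p1_sp", c(1, 2, 3, 1)), paste0("fam_p2_sp", c(1, 2, 3, 1)),
      paste0("fam_c1_sp", c(1, 2, 3, 1))), acc)
  pairs <- expand.grid(q = acc, s = acc, stringsAsFactors = FALSE)
  hits <- tibble::tibble(qseqid = pairs$q, sseqid = pairs$s,
                         bitscore = round(stats::runif(nrow(pairs), 50, 500)),
                         evalue = stats::runif(nrow(pairs)) * 1e-10)
  r1 <- detect_rogues(hits, acc2sp, tax)
  r2 <- detect_rogues(hits[sample(nrow(hits)), ], acc2sp, tax)
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("removing a flagged rogue never flags an unaffected clean query", {
  tax <- make_test_taxonomy()
  acc2sp <- c(Q1 = "fam_p1_sp1", Q2 = "fam_p1_sp2", S1 = "fam_p1_sp3",
              S2 = "fam_p2_sp1", S3 = "fam_p2_sp2", S4 = "fam_p2_sp3")
  h <- hit_rows(
    c("Q1", "S2", 500, 1e-60), c("Q1", "S3", 450, 1e-55),
    c("Q1", "S4", 400, 1e-50), c("Q1", "S1", 300, 1e-40),
    c("Q2", "S1", 500, 1e-60), c("Q2", "S2", 400, 1e-50),
    c("Q2", "S3", 300, 1e-40))
  r <- detect_rogues(h, acc2sp, tax)
  expect_true(r$flagged[r$accession == "Q1"])
  expect_false(r$flagged[r$accession == "Q2"])
  h2 <- h[h$qseqid != "Q1" & h$sseqid != "Q1", ]
  r2 <- detect_rogues(h2, acc2sp, tax)
  expect_false(r2$flagged[r2$accession == "Q2"])
})

test_that("monophyly reporting matches clade structure on rooted trees", {
  tax <- make_test_taxonomy()
  t2s <- c(a1 = "fam_p1_sp1", a2 = "fam_p1_sp2",
           b1 = "fam_p2_sp1", b2 = "fam_p2_sp2")

  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  rep <- monophyly_report(tr, tax, ranks = "family", tip2species = t2s)
  expect_setequal(rep$status, "monophyletic")

  tr <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  rep <- monophyly_report(tr, tax, ranks = "family", tip2species = t2s)
  expect_setequal(rep$status, "non_monophyletic")
  expect_equal(lengths(rep$intruders), c(1L, 1L))

  # single sampled tip is monotypic; a species mapping failure is an error
  t2s1 <- c(a1 = "fam_p1_sp1", b1 = "fam_p2_sp1", b2 = "fam_p2_sp2")
  tr <- ape::read.tree(text = "(a1:1,(b1:1,b2:1):1);")
  rep <- monophyly_report(tr, tax, ranks = "family", tip2species = t2s1)
  expect_equal(rep$status[rep$taxon == "Plainfam1aceae"], "monotypic")
  expect_error(monophyly_report(tr, tax, ranks = "family",
                                tip2species = c(a1 = "nope")),
               "unresolvable")
})

test_that("monophyly agrees with exhaustive split enumeration on random trees", {
  tax <- make_test_taxonomy(n_plain_families = 3, n_species = 4)
  sp_pool <- tax$taxon_id[tax$rank == "species"]
  set.seed(99)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    t2s <- stats::setNames(sample(sp_pool, n, replace = FALSE),
                           tr$tip.label)
    rep <- monophyly_report(tr, tax, ranks = c("genus", "family"),
                            tip2species = t2s)
    lin <- lineage_table(unname(t2s), tax)
    for (r in seq_len(nrow(rep))) {
      members <- names(t2s)[t2s %in% lin$species_id[
        lin[[rep$rank[r]]] == rep$taxon[r]]]
      expected <- if (length(members) == 1L) "monotypic"
        else if (oracle_is_mono(tr, members)) "monophyletic"
        else "non_monophyletic"
      expect_equal(rep$status[r], expected,
                   info = paste("tree", i, rep$taxon[r]))
    }
  }
})

test_that("curated lists apply with exclude-beats-include precedence", {
  recs <- tibble::tibble(accession = c("X1", "X2", "X3"),
                         species_id = "s1", locus = "rbcL",
                         seq = "ACGT")
  out <- apply_curated_lists(recs, exclude_list = "X1")
  expect_equal(out$accession, c("X2", "X3"))
  expect_equal(attr(out, "removed")$reason, "curated_rogue")

  out <- apply_curated_lists(recs, include_list = "X2")
  expect_equal(out$preferred, c(FALSE, TRUE, FALSE))

  out <- apply_curated_lists(recs, exclude_list = "X2", include_list = "X2")
  expect_false("X2" %in% out$accession)
  expect_equal(attr(out, "conflicts"), "X2")

  expect_warning(apply_curated_lists(recs, exclude_list = "NOPE"),
                 "not present")
})
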