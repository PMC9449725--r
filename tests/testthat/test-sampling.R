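rec <- function(accession, locus, species_id, len, voucher = NA,
                publication = NA) {
  tibble::tibble(accession = accession, locus = locus,
                 species_id = species_id,
                 seq = strrep("A", len), voucher = voucher,
                 publication = publication)
}

test_that("species monophyly across gene trees follows the all-trees rule", {
  a2s <- c(x1 = "sp1", x2 = "sp1", y1 = "sp2", z1 = "sp3", z2 = "sp3")

  # species split across two clades in one gene tree is non-monophyletic
  t1 <- ape::unroot(ape::read.tree(text = "((x1:1,y1:1):1,(x2:1,z1:1):1);"))
  # species forming a clade in a second tree stays non-monophyletic overall
  t2 <- ape::unroot(ape::read.tree(text = "((x1:1,x2:1):1,(y1:1,z1:1):1);"))
  m <- classify_species_monophyly(list(a = t1, b = t2), a2s)
  expect_false(m[["sp1"]])
  # single-accession species are vacuously monophyletic
  expect_true(m[["sp2"]])

  m2 <- classify_species_monophyly(list(b = t2), a2s)
  expect_true(m2[["sp1"]])

  # verify against the split-enumeration oracle on a 6-tip tree
  set.seed(3)
  t3 <- ape::rtree(6, tip.label = c("x1", "x2", "y1", "z1", "z2", "w1"))
  a2s6 <- c(x1 = "sp1", x2 = "sp1", y1 = "sp2", z1 = "sp3", z2 = "sp3",
            w1 = "sp4")
  m3 <- classify_species_monophyly(list(t = ape::unroot(t3)), a2s6)
  for (sp in c("sp1", "sp3")) {
    expect_equal(m3[[sp]],
                 oracle_is_mono(ape::unroot(t3), names(a2s6)[a2s6 == sp]))
  }
})

test_that("candidate groups arise from the three concatenation conditions", {
  # monophyletic species: one group of longest-per-locus
  rs <- dplyr::bind_rows(
    rec("A1", "rbcL", "sp1", 1300), rec("A2", "rbcL", "sp1", 1200),
    rec("A3", "atpB", "sp1", 900))
  g <- build_concat_groups(rs, c(sp1 = TRUE))
  mono <- g[g$basis == "monophyly", ]
  m <- mono$members[[1]]
  expect_equal(m[c("rbcL", "atpB")], c(rbcL = "A1", atpB = "A3"))
  expect_equal(mono$total_len, 1300 + 900)
  expect_true(mono$has_rbcL)

  # same voucher across two loci: one voucher-basis group with both
  rs <- dplyr::bind_rows(
    rec("B1", "rbcL", "sp2", 1000, voucher = "Smith 123"),
    rec("B2", "atpB", "sp2", 800, voucher = "Smith 123"))
  g <- build_concat_groups(rs, c(sp2 = FALSE))
  expect_equal(g$basis, c("voucher", "single", "single"))
  expect_equal(sort(unname(g$members[[1]])), c("B1", "B2"))

  # all accessions from one publication
  rs <- dplyr::bind_rows(
    rec("C1", "rbcL", "sp3", 1000, publication = "p1"),
    rec("C2", "matK", "sp3", 700, publication = "p1"))
  g <- build_concat_groups(rs, c(sp3 = FALSE))
  expect_true("publication" %in% g$basis)

  # nothing shared and non-monophyletic: only single groups
  rs <- dplyr::bind_rows(
    rec("D1", "rbcL", "sp4", 1000, voucher = "v1", publication = "p1"),
    rec("D2", "atpB", "sp4", 800, voucher = "v2", publication = "p2"))
  g <- build_concat_groups(rs, c(sp4 = FALSE))
  expect_setequal(g$basis, "single")
  expect_equal(nrow(g), 2L)

  # missing voucher/publication fields never satisfy conditions 2-3
  rs <- dplyr::bind_rows(rec("E1", "rbcL", "sp5", 1000),
                         rec("E2", "atpB", "sp5", 800))
  g <- build_concat_groups(rs, c(sp5 = FALSE))
  expect_setequal(g$basis, "single")
})

test_that("every accession lands in at least one group, none twice within one", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    rs <- purrr::map_dfr(seq_len(n), function(j) {
      rec(paste0("A", j), sample(c("rbcL", "atpB", "matK"), 1), "sp",
          sample(500:1500, 1),
          voucher = sample(c(NA, "v1", "v2"), 1),
          publication = sample(c(NA, "p1"), 1))
    })
    g <- build_concat_groups(rs, stats::setNames(sample(c(TRUE, FALSE), 1), "sp"))
    in_groups <- unlist(lapply(g$members, unname))
    expect_true(all(rs$accession %in% in_groups))
    for (m in g$members) expect_equal(anyDuplicated(unname(m)), 0L)
    for (m in g$members) expect_equal(anyDuplicated(names(m)), 0L)
  }
})

test_that("selection rules S1-S3 and curated preference behave as documented", {
  # S1: rbcL plus another locus beats an rbcL-only single of any length
  rs <- dplyr::bind_rows(
    rec("A1", "rbcL", "sp1", 1000, voucher = "v"),
    rec("A2", "atpB", "sp1", 1400, voucher = "v"),
    rec("A3", "rbcL", "sp1", 1400))
  g <- build_concat_groups(rs, c(sp1 = FALSE))
  sel <- select_sanger_representative(g)
  expect_equal(sel$rule, "S1")
  expect_setequal(unname(sel$members[[1]]), c("A1", "A2"))

  # S2: only rbcL singles -> longest rbcL
  rs <- dplyr::bind_rows(rec("B1", "rbcL", "sp2", 1300),
                         rec("B2", "rbcL", "sp2", 1250))
  sel <- select_sanger_representative(build_concat_groups(rs, c(sp2 = FALSE)))
  expect_equal(sel$rule, "S2")
  expect_equal(unname(sel$members[[1]]), "B1")

  # S3: no rbcL -> greatest total length
  rs <- dplyr::bind_rows(rec("C1", "atpB", "sp3", 900),
                         rec("C2", "matK", "sp3", 1100))
  sel <- select_sanger_representative(build_concat_groups(rs, c(sp3 = FALSE)))
  expect_equal(sel$rule, "S3")
  expect_equal(unname(sel$members[[1]]), "C2")

  # curated preference overrides the automated rules
  rs <- dplyr::bind_rows(rec("D1", "rbcL", "sp4", 1400),
                         rec("D2", "rbcL", "sp4", 900))
  sel <- select_sanger_representative(build_concat_groups(rs, c(sp4 = FALSE)),
                                      curated_preferences = "D2")
  expect_equal(sel$rule, "curated")
  expect_equal(unname(sel$members[[1]]), "D2")
})

test_that("selection matches the literal-rule oracle on random configurations", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(1:4, 1)
    rs <- purrr::map_dfr(seq_len(n), function(j) {
      rec(sprintf("A%02d", j), sample(c("rbcL", "atpB", "matK"), 1), "sp",
          sample(c(800, 1000, 1000, 1200), 1),
          voucher = sample(c(NA, "v1", "v1", "v2"), 1),
          publication = sample(c(NA, "p1", "p1"), 1))
    })
    mono <- stats::setNames(sample(c(TRUE, FALSE), 1), "sp")
    sel <- select_sanger_representative(build_concat_groups(rs, mono))
    orc <- oracle_selection(rs, mono)[["sp"]]
    expect_equal(sel$rule, orc$rule, info = paste("case", i))
    expect_equal(sel$members[[1]][order(names(sel$members[[1]]))],
                 orc$members[order(names(orc$members))],
                 info = paste("case", i), ignore_attr = TRUE)
  }
})

test_that("lengthening the chosen rbcL never changes the S1/S2 selection", {
  rs <- dplyr::bind_rows(
    rec("A1", "rbcL", "sp1", 1000, voucher = "v"),
    rec("A2", "atpB", "sp1", 700, voucher = "v"),
    rec("A3", "rbcL", "sp1", 900))
  sel1 <- select_sanger_representative(build_concat_groups(rs, c(sp1 = FALSE)))
  rs2 <- rs
  rs2$seq[1] <- strrep("A", 1600)
  sel2 <- select_sanger_representative(build_concat_groups(rs2, c(sp1 = FALSE)))
  expect_equal(sel1$members[[1]], sel2$members[[1]], ignore_attr = TRUE)
  expect_equal(sel1$rule, sel2$rule)
})

test_that("plastome selection keeps the specimen with greatest combined length", {
  prec <- function(spec, locus, len)
    tibble::tibble(accession = paste0(spec, "_", locus), specimen = spec,
                   species_id = "sp1", locus = locus, seq = strrep("G", len))
  rs <- dplyr::bind_rows(
    prec("SPEC_A", "rbcL", 1400), prec("SPEC_A", "atpB", 1200),
    prec("SPEC_B", "rbcL", 1500), prec("SPEC_B", "atpB", 1300))
  sel <- select_plastome_representative(rs)
  expect_equal(sel$specimen, "SPEC_B")
  expect_equal(sel$total_len, 2800)
  expect_equal(sel$rule, "plastome")

  # tie: lexicographically smaller specimen
  rs2 <- dplyr::bind_rows(prec("SPEC_B", "rbcL", 1000),
                          prec("SPEC_A", "rbcL", 1000))
  expect_equal(select_plastome_representative(rs2)$specimen, "SPEC_A")

  # single specimen selects itself
  expect_equal(select_plastome_representative(
    prec("ONLY", "rbcL", 500))$specimen, "ONLY")
})

test_that("selection is total and unique per species with candidates", {
  set.seed(41)
  rs <- dplyr::bind_rows(
    rec("A1", "rbcL", "sp1", 1000), rec("B1", "atpB", "sp2", 900),
    rec("B2", "rbcL", "sp2", 800, voucher = "v"),
    rec("C1", "matK", "sp3", 700))
  sel <- select_sanger_representative(build_concat_groups(rs, NULL))
  expect_equal(sort(sel$species_id), c("sp1", "sp2", "sp3"))
  expect_equal(anyDuplicated(sel$species_id), 0L)
})
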