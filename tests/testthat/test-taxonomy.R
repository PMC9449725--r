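test_that("scientific names parse into canonical and authorship parts", {
  p <- parse_scientific_name("Asplenium nidus L.")
  expect_equal(p$genus, "Asplenium")
  expect_equal(p$epithet, "nidus")
  expect_equal(p$authorship, "L.")
  expect_false(p$has_basionym_author)
  expect_false(p$is_hybrid_formula)
  expect_equal(p$annotation, "none")

  p <- parse_scientific_name("Cyathea contaminans (Wall. ex Hook.) Copel.")
  expect_true(p$has_basionym_author)
  expect_equal(p$canonical, "Cyathea contaminans")

  p <- parse_scientific_name("Dryopteris filix-mas var. parallelogramma Kuntze")
  expect_equal(p$infraspecific_rank, "var")
  expect_equal(p$infraspecific_epithet, "parallelogramma")
  expect_equal(p$canonical, "Dryopteris filix-mas var. parallelogramma")
  expect_equal(p$authorship, "Kuntze")
})

test_that("open nomenclature, environmental and hybrid formulas are flagged", {
  expect_equal(parse_scientific_name("Amauropelta sp. aff. rudis")$annotation,
               "aff")
  expect_equal(parse_scientific_name("Pteris cf. vittata")$annotation, "cf")
  expect_equal(parse_scientific_name("uncultured Pteris clone 3")$annotation,
               "environmental")
  expect_true(parse_scientific_name(
    "Equisetum arvense × Equisetum fluviatile")$is_hybrid_formula)
  expect_true(parse_scientific_name(
    "Asplenium nidus x Asplenium australasicum")$is_hybrid_formula)
  # named hybrids with a hybrid sign are not formulas
  expect_false(parse_scientific_name(
    "×Cystocarpium roskamianum")$is_hybrid_formula)
})

test_that("annotation flags agree with a token-regex oracle on many names", {
  genera <- c("Pteris", "Asplenium", "Cyathea", "Adiantum", "Blechnum")
  epithets <- c("vittata", "nidus", "contaminans", "raddianum", "occidentale")
  set.seed(42)
  for (i in 1:50) {
    g <- sample(genera, 1); e <- sample(epithets, 1)
    kind <- sample(c("plain", "aff", "cf"), 1)
    nm <- switch(kind, plain = paste(g, e),
                 aff = paste(g, "aff.", e), cf = paste(g, "cf.", e))
    expected <- if (grepl("(^|\\s)aff\\.(\\s|$)", nm)) "aff"
      else if (grepl("(^|\\s)cf\\.(\\s|$)", nm)) "cf" else "none"
    expect_equal(parse_scientific_name(nm)$annotation, expected, info = nm)
  }
})

test_that("unparseable strings fail loudly", {
  expect_error(parse_scientific_name("   "), "empty")
  expect_error(parse_scientific_name("123 456"), "parse failure")
})

fixture_taxonomy <- function() {
  tibble::tibble(
    taxon_id = c("t1", "t2", "t3", "t4", "t5", "g1", "f1", "o1"),
    scientific_name = c("Cyathea contaminans", "Cyathea australis",
                        "Cyathea contigua", "Alsophila contaminans",
                        "Cyathea contaminans", "Cyathea", "Cyatheaceae",
                        "Cyatheales"),
    authorship = c("(Wall. ex Hook.) Copel.", "(R. Br.) Domin", "Copel.",
                   "Wall.", "Racib.", "", "", ""),
    rank = c(rep("species", 5), "genus", "family", "order"),
    status = c("accepted", "accepted", "accepted", "synonym", "synonym",
               rep("accepted", 3)),
    accepted_id = c(NA, NA, NA, "t1", "t2", NA, NA, NA),
    parent_id = c("g1", "g1", "g1", NA, NA, "f1", "o1", NA)
  )
}

test_that("matching tries exact, canonical, then fuzzy with a distance oracle", {
  tax <- fixture_taxonomy()
  m <- match_name("Cyathea contaminans (Wall. ex Hook.) Copel.", tax)
  expect_equal(m$match_kind, "exact_full")
  expect_equal(m$matched_id, "t1")
  expect_equal(m$distance, 0L)

  # homonym canonical: author similarity picks between t1 and t5
  m <- match_name("Cyathea contaminans Racib.", tax)
  expect_equal(m$matched_id, "t5")
  expect_equal(m$resolved_accepted_id, "t2")

  # misspelling resolves by fuzzy match; verify with exhaustive Levenshtein
  # (the canonical homonym t5 is removed so the best match is unique)
  tax2 <- tax[tax$taxon_id != "t5", ]
  m <- match_name("Cyathea contaminens", tax2, max_distance = 1)
  expect_equal(m$match_kind, "fuzzy")
  d <- vapply(tax2$scientific_name, oracle_lev, numeric(1),
              a = "Cyathea contaminens")
  expect_equal(m$distance, as.integer(min(d)))
  expect_equal(m$matched_id, tax2$taxon_id[which.min(d)])
  expect_equal(m$matched_id, "t1")

  # no match outside the distance budget
  expect_equal(match_name("Dicksonia antarctica", tax)$match_kind, "none")
})

test_that("equally distant candidates are ambiguous, never auto-resolved", {
  tax <- tibble::tibble(
    taxon_id = c("a", "b"),
    scientific_name = c("Pteris vittata", "Pteris vittola"),
    authorship = c("", ""), rank = "species", status = "accepted",
    accepted_id = NA_character_, parent_id = NA_character_)
  # "Pteris vittaka" is distance 1 from vittata and ... check with oracle
  q <- "Pteris vittala"
  d <- vapply(tax$scientific_name, oracle_lev, numeric(1), a = q)
  expect_equal(unname(d), c(1, 1))
  m <- match_name(q, tax, max_distance = 1)
  expect_equal(m$match_kind, "ambiguous")
  expect_true(is.na(m$resolved_accepted_id))
  expect_error(resolve_accepted(m, tax), "ambiguous")
})

test_that("raising max_distance never changes a distance-0 result", {
  tax <- fixture_taxonomy()
  for (nm in tax$scientific_name[tax$rank == "species"]) {
    m0 <- match_name(nm, tax, max_distance = 0)
    m3 <- match_name(nm, tax, max_distance = 3)
    expect_equal(m0$distance, 0L)
    expect_equal(m3$matched_id, m0$matched_id)
    expect_equal(m3$distance, 0L)
  }
})

test_that("resolution over all stored synonyms reproduces accepted_id", {
  tax <- fixture_taxonomy()
  syn <- tax[tax$status == "synonym", ]
  for (i in seq_len(nrow(syn))) {
    m <- match_name(paste(syn$scientific_name[i], syn$authorship[i]), tax)
    expect_equal(resolve_accepted(m, tax), syn$accepted_id[i])
  }
  # idempotence: accepted names resolve to themselves
  acc <- tax[tax$status == "accepted" & tax$rank == "species", ]
  for (i in seq_len(nrow(acc))) {
    m <- match_name(paste(acc$scientific_name[i], acc$authorship[i]), tax)
    expect_equal(resolve_accepted(m, tax), acc$taxon_id[i])
  }
})

test_that("a trinomial never fuzzily matches a binomial", {
  tax <- tibble::tibble(
    taxon_id = "a", scientific_name = "Pteris vittata",
    authorship = "", rank = "species", status = "accepted",
    accepted_id = NA_character_, parent_id = NA_character_)
  m <- match_name("Pteris vittata var. minor", tax, max_distance = 3)
  expect_equal(m$match_kind, "none")
})

test_that("taxonomy validation reports each defect kind", {
  tax <- fixture_taxonomy()
  expect_equal(nrow(validate_taxonomy(tax)), 0L)

  bad <- tax
  bad$accepted_id[bad$taxon_id == "t4"] <- "t5"  # synonym -> synonym
  v <- validate_taxonomy(bad)
  expect_true("synonym_chain" %in% v$kind)

  dup <- dplyr::bind_rows(tax, tax[1, ])
  expect_true("duplicate_id" %in% validate_taxonomy(dup)$kind)

  dang <- tax
  dang$parent_id[1] <- "nope"
  expect_true("dangling_parent" %in% validate_taxonomy(dang)$kind)

  cyc <- tax
  cyc$parent_id[cyc$taxon_id == "o1"] <- "g1"
  expect_true("parent_cycle" %in% validate_taxonomy(cyc)$kind)
})

test_that("taxonomy edits are transactional", {
  tax <- fixture_taxonomy()
  ed <- edit_taxonomy(tax, tibble::tibble(
    taxon_id = "t9", scientific_name = "Cyathea nova", authorship = "",
    rank = "species", status = "accepted", accepted_id = NA_character_,
    parent_id = "g1"))
  expect_true("t9" %in% ed$taxon_id)
  expect_error(edit_taxonomy(tax, tibble::tibble(
    taxon_id = "t9", scientific_name = "Cyathea nova", authorship = "",
    rank = "species", status = "synonym", accepted_id = "t4",
    parent_id = NA_character_)), "rejected")
  expect_equal(nrow(tax), nrow(fixture_taxonomy()))
})

test_that("lineages walk to order and compute family monotypy on the fly", {
  tax <- make_test_taxonomy()
  l <- lineage_of("fam_c1_sp1", tax)
  expect_equal(l$order, "Cyatheales")
  expect_equal(l$family, "Cyatheaceae")
  expect_false(l$is_monotypic_family)
  expect_true(lineage_of("fam_m_sp1", tax)$is_monotypic_family)
  expect_equal(lineage_of("fam_s1_sp1", tax)$suborder, "Saccolomatineae")

  broken <- tax
  broken$parent_id[broken$taxon_id == "gen_c1"] <- NA
  expect_error(lineage_of("fam_c1_sp1", broken), "parent chain")
  expect_error(lineage_of("fam_c1", tax), "not an accepted species")
})

test_that("Darwin Core tables round-trip through TSV and CSV", {
  tax <- fixture_taxonomy()
  for (ext in c("tsv", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_dwc_taxonomy(tax, path)
    back <- read_dwc_taxonomy(path)
    expect_equal(as.data.frame(back), as.data.frame(tax))
  }
})
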