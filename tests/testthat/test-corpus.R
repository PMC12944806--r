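test_that("parse_hpoa reads the tab-separated dialect", {
  txt <- toy_hpoa(c(
    toy_hpoa_row("OMIM:1", "T:2", "7/11"),
    toy_hpoa_row("OMIM:1", "T:3", "30%"),
    toy_hpoa_row("OMIM:2", "T:2", "")
  ))
  ann <- parse_hpoa(c("#comment line", txt))
  expect_equal(nrow(ann), 3L)
  expect_equal(ann$frequency, c("7/11", "30%", NA))

  expect_error(parse_hpoa(paste(c("database_id", "hpo_id", "aspect"),
                                collapse = "\t")),
               "mandatory column")
  expect_warning(
    parse_hpoa(toy_hpoa(toy_hpoa_row("OMIM:1", "T:2", "sometimes"))),
    "unparseable"
  )
})

test_that("filter_phenotypic applies aspect, subtree and NOT filters", {
  onto <- diamond_ontology()
  txt <- toy_hpoa(c(
    toy_hpoa_row("OMIM:1", "D:2", "30%"),
    toy_hpoa_row("OMIM:1", "D:2", "30%", aspect = "I"),
    toy_hpoa_row("OMIM:1", "ZZ:9", "30%"),
    toy_hpoa_row("OMIM:1", "D:3", "30%", qualifier = "NOT")
  ))
  ann <- filter_phenotypic(parse_hpoa(txt), onto)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$hpo_id, "D:2")
  expect_equal(attr(ann, "n_dropped_aspect"), 1L)
  expect_equal(attr(ann, "n_dropped_subtree"), 1L)
  expect_equal(attr(ann, "n_dropped_not"), 1L)

  # subtree membership drops terms outside a restricted ontology
  sub <- restrict_to_subtree(onto, "D:2")
  ann2 <- filter_phenotypic(
    parse_hpoa(toy_hpoa(c(toy_hpoa_row("O:1", "D:3"),
                          toy_hpoa_row("O:1", "D:4")))), sub)
  expect_equal(ann2$hpo_id, "D:4")
})

test_that("resolve_frequency normalises the four formats", {
  r <- resolve_frequency(c("7/11", "30%", "HP:0040283", NA))
  expect_equal(r$value, c(7 / 11, 0.30, 0.17, 0.5))
  expect_equal(r$weight, c(11, NA, NA, NA))
  expect_equal(r$lo[3], 0.05)
  expect_equal(r$hi[3], 0.29)
  # sensitivity presets for missing frequencies
  expect_equal(resolve_frequency(NA, unknown_default = 0.01)$value, 0.01)
  expect_equal(resolve_frequency(NA, unknown_default = 1.0)$value, 1.0)
  expect_error(resolve_frequency("HP:9999999"), "unknown frequency-class")
})

test_that("merge_duplicates follows the three rules", {
  # rule 1: fractions pool with denominators as weights
  fr <- resolve_frequency(c("7/11", "3/5"))
  expect_equal(merge_duplicates(fr)$value, (7 + 3) / (11 + 5))
  expect_equal(merge_duplicates(fr)$value, 0.625)

  # rule 2: smallest interval compatible with all values
  mix <- resolve_frequency(c("HP:0040283", "30%"))
  m <- merge_duplicates(mix)
  expect_equal(c(m$lo, m$hi), c(0.05, 0.30))   # disjoint: spanning hull
  expect_equal(m$value, 0.175)
  overlap <- resolve_frequency(c("HP:0040283", "10%"))
  expect_equal(merge_duplicates(overlap)$value, 0.10)  # intersection is {0.1}

  # rule 3: arithmetic mean otherwise
  pct <- resolve_frequency(c("30%", "50%"))
  expect_equal(merge_duplicates(pct)$value, 0.4)

  # idempotence and permutation invariance
  v <- resolve_frequency(c("40%", "40%"))
  expect_equal(merge_duplicates(v)$value, 0.4)
  perm <- resolve_frequency(c("7/11", "3/5", "HP:0040282"))
  for (p in list(1:3, 3:1, c(2, 1, 3))) {
    expect_equal(merge_duplicates(perm[p, ]), merge_duplicates(perm))
  }
  expect_error(merge_duplicates(perm[0, ]), "at least one")
})

test_that("map_to_mondo unifies identifiers through xrefs", {
  mondo <- parse_obo(c(
    "[Term]", "id: MONDO:0000001", "name: disease root",
    "[Term]", "id: MONDO:0000010", "name: d10", "is_a: MONDO:0000001",
    "xref: OMIM:111",
    "[Term]", "id: MONDO:0000020", "name: d20", "is_a: MONDO:0000001",
    "xref: OMIM:222", "xref: ORPHA:9",
    "[Term]", "id: MONDO:0000030", "name: d30", "is_a: MONDO:0000001",
    "xref: OMIM:222"
  ))
  m <- map_to_mondo("OMIM:111", mondo)
  expect_equal(m$unified_id, "MONDO:0000010")
  expect_true(m$mapped)
  m2 <- map_to_mondo("OMIM:999", mondo)
  expect_equal(m2$unified_id, "OMIM:999")
  expect_false(m2$mapped)
  # ambiguous xref resolves to the lexicographically smallest id
  expect_warning(m3 <- map_to_mondo("OMIM:222", mondo), "multiple")
  expect_equal(m3$unified_id, "MONDO:0000020")
})

test_that("build_corpus groups, merges and unifies", {
  onto <- diamond_ontology()
  txt <- toy_hpoa(c(
    toy_hpoa_row("OMIM:1", "D:2", "7/11"),
    toy_hpoa_row("OMIM:1", "D:2", "3/5"),
    toy_hpoa_row("OMIM:1", "D:3", "")
  ))
  ann <- filter_phenotypic(parse_hpoa(txt), onto)
  corpus <- build_corpus(ann, onto)
  expect_equal(nrow(corpus), 2L)
  expect_equal(corpus$frequency[corpus$term_id == "D:2"], 0.625)
  expect_equal(corpus$frequency[corpus$term_id == "D:3"], 0.5)

  # two source ids mapping to one MONDO id union their annotations
  mondo <- parse_obo(c(
    "[Term]", "id: MONDO:0000001", "name: root",
    "[Term]", "id: MONDO:0000010", "name: d", "is_a: MONDO:0000001",
    "xref: OMIM:7", "xref: ORPHA:7"
  ))
  txt2 <- toy_hpoa(c(
    toy_hpoa_row("OMIM:7", "D:2", "7/11"),
    toy_hpoa_row("ORPHA:7", "D:2", "3/5"),
    toy_hpoa_row("ORPHA:7", "D:4", "10%")
  ))
  ann2 <- filter_phenotypic(parse_hpoa(txt2), onto)
  corpus2 <- build_corpus(ann2, onto, mondo = mondo)
  expect_equal(unique(corpus2$disease_id), "MONDO:0000010")
  expect_equal(nrow(corpus2), 2L)
  expect_equal(corpus2$frequency[corpus2$term_id == "D:2"], 0.625)
})

test_that("corpus frequencies stay in [0,1] and building is deterministic", {
  cfg <- synthetic_config(n_terms = 50, n_diseases = 25,
                          annotations_per_disease = c(3, 8), seed = 7)
  g <- generate_ontology(cfg)
  ann <- filter_phenotypic(parse_hpoa(generate_corpus(g, cfg)), g)
  c1 <- build_corpus(ann, g)
  c2 <- build_corpus(ann, g)
  expect_true(all(c1$frequency >= 0 & c1$frequency <= 1))
  expect_identical(as.data.frame(c1), as.data.frame(c2))

  # distinct pairs in == pairs out
  pairs_in <- nrow(unique(data.frame(ann$database_id, ann$hpo_id)))
  expect_equal(nrow(c1), pairs_in)

  # round trip through the TSV writer
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(c1, path)
  expect_equal(as.data.frame(read_corpus(path)), as.data.frame(c1),
               ignore_attr = TRUE)
})
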