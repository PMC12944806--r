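# Diamond fixture with a hand-computable IC table:
# root D:0 <- D:1 <- {D:2, D:3} <- D:4; four diseases annotated to
# D:2, D:3, D:4, D:1 give p = (2/4, 2/4, 1/4, 1) for (D:2, D:3, D:4, D:1).
diamond_ic <- function() {
  onto <- diamond_ontology()
  corpus <- tibble::tibble(
    disease_id = c("X1", "X2", "X3", "X4"),
    term_id = c("D:2", "D:3", "D:4", "D:1"),
    frequency = 0.5
  )
  list(onto = onto, corpus = corpus, ic = compute_ic(onto, corpus))
}

test_that("jaccard matches set arithmetic and its conventions", {
  expect_equal(jaccard_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_similarity(c("a"), c("b")), 0)
  expect_equal(jaccard_similarity(c("a", "b"), c("a", "c")), 1 / 3)
  expect_equal(jaccard_similarity(character(0), character(0)), 0)
  set.seed(11)
  for (i in 1:100) {
    a <- sample(letters, sample(0:8, 1))
    b <- sample(letters, sample(0:8, 1))
    expect_equal(jaccard_similarity(a, b), naive_jaccard(a, b))
    expect_equal(jaccard_similarity(a, b), jaccard_similarity(b, a))
  }
})

test_that("resnik term similarity is the most informative common ancestor", {
  f <- diamond_ic()
  icv <- setNames(f$ic$ic, f$ic$term_id)
  expect_equal(resnik_term(f$onto, f$ic, "D:2", "D:2"), icv[["D:2"]])
  expect_equal(resnik_term(f$onto, f$ic, "D:2", "D:3"), 0)   # only root-level shared
  expect_equal(resnik_term(f$onto, f$ic, "D:2", "D:4"), log(2))
  set.seed(12)
  g <- generate_ontology(synthetic_config(n_terms = 30, seed = 3))
  cfg <- synthetic_config(n_terms = 30, n_diseases = 15,
                          annotations_per_disease = c(2, 5), seed = 3)
  corpus <- build_corpus(filter_phenotypic(parse_hpoa(generate_corpus(g, cfg)), g), g)
  ic <- compute_ic(g, corpus)
  for (i in 1:20) {
    xy <- sample(term_ids(g), 2)
    expect_equal(resnik_term(g, ic, xy[1], xy[2]),
                 naive_resnik_term(g, ic, xy[1], xy[2]))
  }
})

test_that("profile-level resnik combines the pair grid as stated", {
  f <- diamond_ic()
  ic_x <- log(2)  # ic(D:2)
  expect_equal(resnik_profile(f$onto, f$ic, "D:2", "D:2"), ic_x)
  # A = {x}, B = {x, y} with sim(x, y) = 0
  expect_equal(resnik_profile(f$onto, f$ic, "D:2", c("D:2", "D:3"),
                              combine = "avg"), ic_x / 2)
  expect_equal(resnik_profile(f$onto, f$ic, "D:2", c("D:2", "D:3"),
                              combine = "bma"),
               (ic_x + ic_x / 2) / 2)
  # symmetry
  for (combine in c("avg", "bma")) {
    expect_equal(
      resnik_profile(f$onto, f$ic, c("D:2", "D:4"), c("D:3", "D:1"), combine),
      resnik_profile(f$onto, f$ic, c("D:3", "D:1"), c("D:2", "D:4"), combine)
    )
  }
  expect_error(resnik_profile(f$onto, f$ic, character(0), "D:2"), "non-empty")
})

test_that("graphic similarity is the shared-IC ratio over expanded sets", {
  f <- diamond_ic()
  expect_equal(graphic_similarity(f$onto, f$ic, c("D:2", "D:4"),
                                  c("D:2", "D:4")), 1)
  expect_equal(graphic_similarity(f$onto, f$ic, "D:2", "D:3"), 0)
  # hand-summed ratio: intersection ic = log 2, union ic = 4 log 2
  expect_equal(graphic_similarity(f$onto, f$ic, "D:4", "D:2"), 1 / 4)
  expect_equal(graphic_similarity(f$onto, f$ic, "D:4", "D:2"),
               graphic_similarity(f$onto, f$ic, "D:2", "D:4"))
  # all-zero ic in the union -> 0 with a warning
  onto2 <- parse_obo(c("[Term]", "id: R:0", "name: r",
                       "[Term]", "id: R:1", "name: a", "is_a: R:0"))
  corpus2 <- tibble::tibble(disease_id = "Z", term_id = "R:1", frequency = 1)
  ic2 <- compute_ic(onto2, corpus2)   # every term has p = 1, ic = 0
  expect_warning(v <- graphic_similarity(onto2, ic2, "R:1", "R:1"),
                 "denominator")
  expect_equal(v, 0)
})

test_that("query expansion reproduces the worked example", {
  mt <- muscle_tone_ontology()
  prof <- tibble::tibble(term_id = c("HP:0001257", "HP:0001252"),
                         frequency = c(0.8, 0.6))
  expect_equal(term_distance(mt, "HP:0001257", "HP:0006895"), 3)
  expect_equal(term_distance(mt, "HP:0001252", "HP:0006895"), 4)
  ex <- expand_query(prof, mt, alpha = 0.5)
  llh <- ex[ex$term_id == "HP:0006895", ]
  # Spasticity (d = 3) beats Hypotonia (d = 4): f = 0.8 * 0.5^3
  expect_equal(llh$seed_term, "HP:0001257")
  expect_equal(llh$distance, 3)
  expect_equal(llh$frequency, 0.8 * 0.5^3)
  expect_equal(llh$frequency / 0.8, 0.125)
  # seeds keep their own frequency
  expect_equal(ex$frequency[ex$term_id == "HP:0001257"], 0.8)
  expect_equal(ex$frequency[ex$term_id == "HP:0001252"], 0.6)
})

test_that("query expansion limits: alpha 0 and 1, monotonicity, ties", {
  mt <- muscle_tone_ontology()
  prof <- tibble::tibble(term_id = c("HP:0001257", "HP:0001252"),
                         frequency = c(0.8, 0.6))
  ex0 <- expand_query(prof, mt, alpha = 0)
  expect_setequal(ex0$term_id[ex0$frequency > 0], prof$term_id)
  expect_equal(ex0$frequency[ex0$term_id == "HP:0001257"], 0.8)
  ex1 <- expand_query(prof, mt, alpha = 1)
  joined <- merge(ex1, prof, by.x = "seed_term", by.y = "term_id")
  expect_equal(joined$frequency.x, joined$frequency.y)
  # nobody exceeds the strongest seed; f antitone in d for a fixed seed
  for (a in c(0.3, 0.5, 0.9)) {
    ex <- expand_query(prof, mt, alpha = a)
    expect_true(all(ex$frequency <= max(prof$frequency) + 1e-12))
    for (s in prof$term_id) {
      sub <- ex[ex$seed_term == s, ]
      sub <- sub[order(sub$distance), ]
      expect_true(all(diff(sub$frequency) <= 1e-12))
    }
  }
  # increasing alpha never decreases any expanded frequency
  e1 <- expand_query(prof, mt, alpha = 0.3)
  e2 <- expand_query(prof, mt, alpha = 0.7)
  expect_true(all(e2$frequency - e1$frequency >= -1e-12))
  # equidistant seeds: the larger resulting frequency wins
  y_onto <- parse_obo(c("[Term]", "id: Y:0", "name: r",
                        "[Term]", "id: Y:1", "name: a", "is_a: Y:0",
                        "[Term]", "id: Y:2", "name: b", "is_a: Y:0"))
  tie <- expand_query(tibble::tibble(term_id = c("Y:1", "Y:2"),
                                     frequency = c(0.2, 0.9)),
                      y_onto, alpha = 0.5)
  expect_equal(tie$seed_term[tie$term_id == "Y:0"], "Y:2")
  expect_equal(tie$frequency[tie$term_id == "Y:0"], 0.9 * 0.5)
  expect_error(expand_query(tibble::tibble(term_id = "HP:9999999",
                                           frequency = 0.5), mt),
               "unknown term")
})

test_that("tf-idf weights match a hand computation on a 3-document corpus", {
  corpus <- tibble::tibble(
    disease_id = c("d1", "d1", "d2", "d3"),
    disease_name = "toy",
    term_id = c("t1", "t2", "t1", "t3"),
    frequency = c(0.5, 1.0, 0.2, 0.4)
  )
  query <- tibble::tibble(term_id = c("t2", "t4"), frequency = c(0.9, 0.3))
  v <- tfidf_vectors(corpus, query)
  idf <- function(df) log((1 + 3) / (1 + df)) + 1
  expect_equal(unname(v$idf["t1"]), idf(2))
  expect_equal(unname(v$idf["t2"]), idf(1))
  expect_equal(unname(v$idf["t4"]), idf(0))  # absent from corpus, smoothed
  expect_equal(unname(v$disease_matrix["d1", "t1"]), 0.5 * idf(2))
  expect_equal(unname(v$disease_matrix["d2", "t1"]), 0.2 * idf(2))
  expect_equal(unname(v$disease_matrix["d3", "t3"]), 0.4 * idf(1))
  expect_equal(unname(v$query["t2"]), 0.9 * idf(1))
  # term present in every document sits at the idf floor for N = 3
  corpus_all <- dplyr::mutate(corpus, term_id = "t1")
  v2 <- tfidf_vectors(dplyr::distinct(corpus_all, disease_id,
                                      .keep_all = TRUE), query)
  expect_equal(unname(v2$idf["t1"]), idf(3))
  expect_true(all(v2$idf >= idf(3)))
  # binary tf option
  vb <- tfidf_vectors(corpus, query, tf = "binary")
  expect_equal(unname(vb$disease_matrix["d1", "t1"]), idf(2))
})

test_that("cosine similarity behaves on the textbook cases", {
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  u <- c(0.3, 0.7, 0.1)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)
})

test_that("score_all ranks a planted clone first and respects bounds", {
  cfg <- synthetic_config(n_terms = 80, n_diseases = 40,
                          annotations_per_disease = c(3, 10),
                          n_query_terms = 6, seed = 5)
  g <- generate_ontology(cfg)
  planted <- plant_query(generate_corpus(g, cfg), g, cfg)
  corpus <- build_corpus(filter_phenotypic(parse_hpoa(planted$hpoa), g), g)
  scores <- score_all(corpus, planted$profile, g,
                      methods = c("jaccard", "resnik_bma", "resnik_avg",
                                  "graphic", "tfidf", "tfidf_qe"))
  clone <- planted$answer_key$clone_id
  sc <- function(m) scores$score[scores$method == m]
  for (m in c("jaccard", "graphic")) {
    expect_true(all(sc(m) >= 0 & sc(m) <= 1))
    expect_equal(scores$score[scores$method == m &
                                scores$disease_id == clone], 1)
  }
  expect_true(all(sc("resnik_bma") >= 0))
  for (m in c("jaccard", "resnik_bma", "graphic", "tfidf", "tfidf_qe")) {
    sub <- scores[scores$method == m, ]
    expect_equal(sub$disease_id[which.max(sub$score)], clone)
  }
  # query expansion leaves no zero-score disease on a connected ontology
  expect_equal(sum(sc("tfidf_qe") == 0), 0)
  expect_error(score_all(corpus, planted$profile, g, methods = "lin"),
               "unknown method")
})

test_that("with alpha = 0, expanded tf-idf equals plain tf-idf", {
  cfg <- synthetic_config(n_terms = 60, n_diseases = 20,
                          annotations_per_disease = c(3, 8),
                          n_query_terms = 5, seed = 9)
  g <- generate_ontology(cfg)
  planted <- plant_query(generate_corpus(g, cfg), g, cfg)
  corpus <- build_corpus(filter_phenotypic(parse_hpoa(planted$hpoa), g), g)
  s <- score_all(corpus, planted$profile, g,
                 methods = c("tfidf", "tfidf_qe"), alpha = 0)
  wide <- tidyr::pivot_wider(s, names_from = "method",
                             values_from = "score")
  expect_equal(wide$tfidf_qe, wide$tfidf, tolerance = 1e-12)
})

test_that("single-disease corpus yields one row per method", {
  onto <- diamond_ontology()
  corpus <- build_corpus(
    filter_phenotypic(parse_hpoa(toy_hpoa(toy_hpoa_row("O:1", "D:2", "50%"))),
                      onto), onto)
  prof <- tibble::tibble(term_id = "D:4", frequency = 0.5)
  s <- score_all(corpus, prof, onto)
  expect_equal(nrow(s), 5L)
  expect_equal(sort(unique(s$method)),
               sort(c("jaccard", "resnik_bma", "graphic", "tfidf", "tfidf_qe")))
})
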