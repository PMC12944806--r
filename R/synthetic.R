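# Seeded synthetic data: random rooted DAG ontologies, HPOA-dialect
# annotation corpora with the four heterogeneous frequency formats, and
# query profiles with planted diseases of known similarity structure
# (clone / partial overlap / ancestor shift), so every pipeline stage is
# testable without downloading real ontology releases.

#' Configuration for the synthetic-data generator
#'
#' Bundles the knobs shared by [generate_ontology()], [generate_corpus()]
#' and [plant_query()]. The defaults emulate the statistical shape of a
#' real disease-annotation corpus at desk scale: diseases annotated with
#' 3--50 terms drawn with popularity bias (a power law over term indices,
#' which gives TF-IDF a broad document-frequency spread), underlying
#' frequencies from a Beta(2, 2), reported in the four HPOA formats —
#' fractions (with denominators 5--200, so duplicate merging sees unequal
#' weights), percentages, frequency-class terms and missing cells — in
#' proportions close to the roughly one-quarter missing rate of the real
#' annotation file.
#'
#' @param n_terms Number of ontology terms (including the root).
#' @param max_parents Maximum parents per non-root term.
#' @param n_diseases Number of background diseases.
#' @param annotations_per_disease Inclusive range of term counts drawn per
#'   disease.
#' @param frequency_mix Proportions (summing to 1) of the `fraction`,
#'   `percent`, `class`, `absent` frequency formats.
#' @param duplicate_fraction Fraction of disease-term pairs that receive a
#'   second, conflicting frequency annotation.
#' @param n_query_terms Number of seed terms in the generated query.
#' @param overlap_fraction Fraction `q` of query terms shared by each
#'   planted overlap disease.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A `phen_config` list.
#' @export
synthetic_config <- function(n_terms = 200, max_parents = 3,
                             n_diseases = 200,
                             annotations_per_disease = c(3, 50),
                             frequency_mix = c(fraction = 0.35,
                                               percent = 0.20,
                                               class = 0.19,
                                               absent = 0.26),
                             duplicate_fraction = 0.1,
                             n_query_terms = 15,
                             overlap_fraction = 0.5,
                             seed = 1) {
  stopifnot(n_terms >= 2, max_parents >= 1,
            abs(sum(frequency_mix) - 1) < 1e-8,
            overlap_fraction >= 0, overlap_fraction <= 1)
  structure(list(
    n_terms = n_terms, max_parents = max_parents, n_diseases = n_diseases,
    annotations_per_disease = annotations_per_disease,
    frequency_mix = frequency_mix,
    duplicate_fraction = duplicate_fraction,
    n_query_terms = n_query_terms, overlap_fraction = overlap_fraction,
    seed = seed
  ), class = "phen_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

syn_term_id <- function(i) sprintf("ST:%07d", i)

# sample() that never falls into the scalar-x trap
resample <- function(x, size, ...) x[sample.int(length(x), size, ...)]

#' Generate a random rooted ontology DAG
#'
#' Term `i > 1` draws between 1 and `max_parents` parents uniformly among
#' the earlier terms `1..i-1`, which guarantees acyclicity and a single
#' root while producing multi-parent (diamond) structure. Deterministic
#' per seed.
#'
#' @param config A [synthetic_config()].
#' @return A `phen_ontology`.
#' @export
generate_ontology <- function(config = synthetic_config()) {
  n <- config$n_terms
  with_seed(config$seed, {
    lines <- c(
      "format-version: 1.2",
      "", "[Term]", sprintf("id: %s", syn_term_id(1)), "name: synthetic root"
    )
    for (i in seq(2L, n)) {
      k <- sample.int(min(config$max_parents, i - 1L), 1L)
      parents <- sort(sample.int(i - 1L, k))
      lines <- c(lines,
        "", "[Term]", sprintf("id: %s", syn_term_id(i)),
        sprintf("name: synthetic term %d", i),
        sprintf("is_a: %s", syn_term_id(parents))
      )
    }
    parse_obo(lines)
  })
}

format_frequency <- function(f, kind) {
  switch(kind,
    fraction = {
      d <- sample(5:200, 1L)
      sprintf("%d/%d", round(f * d), d)
    },
    percent = sprintf("%d%%", round(f * 100)),
    class = {
      cls <- hpo_frequency_classes[hpo_frequency_classes$lo <
                                     hpo_frequency_classes$hi, ]
      hit <- which(f >= cls$lo & f <= cls$hi)
      if (length(hit) == 0L) hit <- which.min(abs((cls$lo + cls$hi) / 2 - f))
      cls$term_id[hit[1]]
    },
    absent = ""
  )
}

hpoa_header <- paste(
  c("database_id", "disease_name", "qualifier", "hpo_id", "reference",
    "evidence", "onset", "frequency", "sex", "modifier", "aspect",
    "biocuration"),
  collapse = "\t"
)

hpoa_row <- function(disease_id, disease_name, term, frequency) {
  paste(disease_id, disease_name, "", term, "PMID:0", "TAS", "", frequency,
        "", "", "P", "SYN[2026]", sep = "\t")
}

#' Generate a synthetic annotation corpus in the HPOA dialect
#'
#' Each disease draws its term count uniformly from
#' `annotations_per_disease` and its terms without replacement with
#' popularity bias (term `i` has weight `1/i`). Underlying frequencies are
#' Beta(2, 2) draws, emitted in one of the four HPOA frequency formats per
#' `frequency_mix`; a `duplicate_fraction` of pairs gets a second
#' conflicting annotation so duplicate resolution is exercised. The output
#' is raw HPOA text that round-trips through [parse_hpoa()].
#'
#' @param ontology A `phen_ontology` (typically from
#'   [generate_ontology()]).
#' @param config A [synthetic_config()].
#' @return Character vector of HPOA lines (header comment + column header
#'   + rows).
#' @export
generate_corpus <- function(ontology, config = synthetic_config()) {
  terms <- sort(term_ids(ontology))
  rng <- config$annotations_per_disease
  if (rng[1] > length(terms)) {
    rlang::abort("annotations_per_disease exceeds the number of ontology terms")
  }
  w <- 1 / seq_along(terms)
  with_seed(config$seed + 1L, {
    rows <- character(0)
    for (i in seq_len(config$n_diseases)) {
      did <- sprintf("SRC:%05d", i)
      dname <- sprintf("synthetic disease %d", i)
      k <- resample(seq(rng[1], min(rng[2], length(terms))), 1L)
      dterms <- resample(terms, k, prob = w)
      f <- stats::rbeta(k, 2, 2)
      kinds <- sample(names(config$frequency_mix), k, replace = TRUE,
                      prob = config$frequency_mix)
      for (j in seq_len(k)) {
        rows <- c(rows, hpoa_row(did, dname, dterms[j],
                                 format_frequency(f[j], kinds[j])))
        if (stats::runif(1) < config$duplicate_fraction) {
          f2 <- stats::rbeta(1, 2, 2)
          k2 <- sample(names(config$frequency_mix), 1L,
                       prob = config$frequency_mix)
          rows <- c(rows, hpoa_row(did, dname, dterms[j],
                                   format_frequency(f2, k2)))
        }
      }
    }
    c("#description: synthetic annotation corpus", hpoa_header, rows)
  })
}

#' Plant a query and diseases of known similarity structure in a corpus
#'
#' Builds a query profile from seeded ontology terms and appends planted
#' diseases to the corpus:
#' \describe{
#'   \item{clone}{identical term set and frequencies — must rank first
#'     under every similarity measure;}
#'   \item{overlap}{a fraction `q` of the query terms plus random
#'     background terms — should outrank background diseases;}
#'   \item{ancestor_shift}{every query term replaced by one of its
#'     parents — zero direct overlap (so Jaccard 0) but shared ancestry,
#'     separating graph-aware measures from exact-overlap ones.}
#' }
#' Query terms are chosen at depth >= 2 and so that the parent-shifted set
#' is disjoint from the query itself. The answer key records the planted
#' ids and the intended recovery ordering clone > overlap > background.
#'
#' @param corpus_hpoa Character vector of HPOA lines
#'   ([generate_corpus()]).
#' @param ontology The `phen_ontology` the corpus annotates.
#' @param config A [synthetic_config()].
#' @return A list: `profile` (a `phen_profile`), `hpoa` (corpus lines with
#'   planted diseases appended), `answer_key` (list of planted ids and
#'   query terms).
#' @export
plant_query <- function(corpus_hpoa, ontology, config = synthetic_config()) {
  n_q <- config$n_query_terms
  with_seed(config$seed + 2L, {
    depths <- igraph::distances(ontology$graph, to = ontology$root,
                                mode = "out")[, 1]
    cand <- sample(names(depths)[depths >= 2])
    qterms <- character(0); shifted <- character(0)
    for (t in cand) {
      if (length(qterms) >= n_q) break
      parents <- igraph::V(ontology$graph)$name[
        as.integer(igraph::neighbors(ontology$graph, t, mode = "out"))
      ]
      p <- sort(parents)[1]
      if (t %in% shifted || p %in% qterms || p %in% shifted || t == p) next
      qterms <- c(qterms, t)
      shifted <- c(shifted, p)
    }
    if (length(qterms) < n_q) {
      rlang::abort("ontology too shallow to draw the requested query terms")
    }
    # two decimals so the planted clone's n/100 fractions reproduce the
    # query frequencies exactly; clamped away from 0 and 1
    qfreq <- pmin(pmax(round(stats::rbeta(n_q, 2, 2), 2), 0.01), 0.99)

    profile <- tibble::tibble(
      symptom_label = sprintf("query symptom %d", seq_len(n_q)),
      term_id = qterms, frequency = qfreq
    )
    attr(profile, "label") <- "synthetic query"
    attr(profile, "n_patients") <- NA_integer_
    class(profile) <- c("phen_profile", class(profile))

    n_overlap <- max(1L, round(config$overlap_fraction * n_q))
    if (config$overlap_fraction * n_q < 1 && config$overlap_fraction > 0) {
      rlang::warn("overlap fraction rounds up to a single shared term")
    }
    bg_terms <- setdiff(sort(term_ids(ontology)),
                        c(qterms, ontology$root))
    overlap_terms <- c(
      resample(qterms, n_overlap),
      resample(setdiff(bg_terms, shifted), n_q - n_overlap)
    )

    planted <- list(
      clone = list(id = "PLANT:CLONE", terms = qterms, freq = qfreq),
      overlap = list(id = "PLANT:OVERLAP", terms = overlap_terms,
                     freq = pmin(pmax(round(stats::rbeta(n_q, 2, 2), 2),
                                      0.01), 0.99)),
      ancestor_shift = list(id = "PLANT:SHIFT", terms = shifted,
                            freq = qfreq)
    )
    rows <- unlist(lapply(planted, function(p) {
      vapply(seq_along(p$terms), function(j) {
        hpoa_row(p$id, tolower(p$id), p$terms[j],
                 sprintf("%d/100", round(p$freq[j] * 100)))
      }, character(1))
    }), use.names = FALSE)

    list(
      profile = profile,
      hpoa = c(corpus_hpoa, rows),
      answer_key = list(
        clone_id = "PLANT:CLONE",
        overlap_id = "PLANT:OVERLAP",
        shift_id = "PLANT:SHIFT",
        query_terms = qterms,
        shifted_terms = shifted,
        expected_order = c("PLANT:CLONE", "PLANT:OVERLAP", "background")
      )
    )
  })
}

#' Generate a synthetic disease ontology with a category layer
#'
#' Reuses the random-DAG generator but designates the children of the root
#' as high-level disease categories, mirroring how the main disease
#' classes sit directly under the root of a disease ontology; used to test
#' [classify_categories()] without the real file.
#'
#' @param config A [synthetic_config()]; `n_terms` should comfortably
#'   exceed `n_categories`.
#' @param n_categories Number of category terms attached directly to the
#'   root.
#' @return A `phen_ontology` whose root children are the categories.
#' @export
generate_disease_ontology <- function(config = synthetic_config(),
                                      n_categories = 8) {
  n <- config$n_terms
  stopifnot(n > n_categories + 1)
  with_seed(config$seed + 3L, {
    lines <- c("format-version: 1.2",
               "", "[Term]", sprintf("id: %s", syn_term_id(1)),
               "name: disease root")
    for (i in seq(2L, n_categories + 1L)) {
      lines <- c(lines, "", "[Term]", sprintf("id: %s", syn_term_id(i)),
                 sprintf("name: category %d", i - 1L),
                 sprintf("is_a: %s", syn_term_id(1)))
    }
    for (i in seq(n_categories + 2L, n)) {
      k <- sample.int(config$max_parents, 1L)
      parents <- unique(resample(seq(2L, i - 1L), min(k, i - 2L)))
      lines <- c(lines, "", "[Term]", sprintf("id: %s", syn_term_id(i)),
                 sprintf("name: synthetic disease %d", i),
                 sprintf("is_a: %s", syn_term_id(parents)))
    }
    parse_obo(lines)
  })
}
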