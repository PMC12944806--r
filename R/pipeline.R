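# End-to-end pipeline: ingest ontology + annotations + query profile,
# score, rank, compare rankings, aggregate, classify. Each run writes its
# tables and a manifest (config + input checksums) into a fresh directory,
# so reruns are reproducible and inputs are never mutated.

#' Pipeline configuration
#'
#' @param hp_obo Path to the phenotype ontology OBO file.
#' @param hpoa Path to the HPOA annotation file.
#' @param profile Path to the query profile TSV.
#' @param mondo_obo Optional path to the disease ontology OBO file (enables
#'   identifier unification and category classification).
#' @param phenotype_root Optional term id of the phenotypic-abnormality
#'   subtree to restrict the ontology to (`NULL` uses the whole file).
#' @param unknown_default Frequency assigned to annotations without one;
#'   0.5 by default, with 0.01 and 1.0 as the sensitivity-analysis presets.
#' @param alpha Query-expansion decay factor.
#' @param methods Similarity methods to score and rank with.
#' @param consensus_methods Methods entering the equal-weight consensus
#'   (the plain TF-IDF ranking is superseded by its query-expanded
#'   counterpart there).
#' @param k Number of top diseases classified into categories.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed drives demo-mode data generation).
#' @return A validated `phen_pipeline_config` list.
#' @export
pipeline_config <- function(hp_obo, hpoa, profile, mondo_obo = NULL,
                            phenotype_root = NULL,
                            unknown_default = 0.5, alpha = 0.5,
                            methods = c("jaccard", "resnik_bma", "graphic",
                                        "tfidf", "tfidf_qe"),
                            consensus_methods = c("jaccard", "resnik_bma",
                                                  "graphic", "tfidf_qe"),
                            k = 50, seed = 1) {
  stopifnot(unknown_default >= 0, unknown_default <= 1,
            alpha >= 0, alpha <= 1, k >= 1)
  bad <- setdiff(c(methods, consensus_methods), phen_methods)
  if (length(bad) > 0L) {
    rlang::abort(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")),
                 class = "phen_config_error")
  }
  for (p in c(hp_obo, hpoa, profile, mondo_obo)) {
    if (!file.exists(p)) {
      rlang::abort(sprintf("input file not found: %s", p),
                   class = "phen_config_error")
    }
  }
  structure(list(
    hp_obo = hp_obo, hpoa = hpoa, profile = profile, mondo_obo = mondo_obo,
    phenotype_root = phenotype_root, unknown_default = unknown_default,
    alpha = alpha, methods = methods,
    consensus_methods = consensus_methods, k = k, seed = seed
  ), class = "phen_pipeline_config")
}

#' Run the full similarity pipeline
#'
#' Ingests the configured inputs, scores every corpus disease against the
#' query under each method, ranks, computes the pairwise weighted-tau
#' matrix, aggregates the consensus ranking and (when a disease ontology
#' is configured) classifies the top diseases into its high-level
#' categories. All tables are written to `out_dir` together with a
#' `manifest.json` recording the configuration and input checksums;
#' dropped-annotation, unmapped-id and zero-score counts are reported via
#' messages.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; created, and refused if it already
#'   contains a manifest (runs are write-once).
#' @return Invisibly, a list with the in-memory results: `corpus`,
#'   `profile`, `scores`, `ranking`, `tau`, `consensus`, `categories`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "phen_pipeline_config"))
  if (file.exists(file.path(out_dir, "manifest.json"))) {
    rlang::abort("output directory already holds a run; refusing to overwrite",
                 class = "phen_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  onto <- parse_obo(config$hp_obo)
  if (!is.null(config$phenotype_root)) {
    onto <- restrict_to_subtree(onto, config$phenotype_root)
  }
  mondo <- if (!is.null(config$mondo_obo)) parse_obo(config$mondo_obo)
  ann <- parse_hpoa(config$hpoa)
  ann <- filter_phenotypic(ann, onto)
  message(sprintf(
    "ingest: dropped %d non-phenotypic, %d out-of-subtree, %d NOT-qualified annotation(s)",
    attr(ann, "n_dropped_aspect"), attr(ann, "n_dropped_subtree"),
    attr(ann, "n_dropped_not")
  ))
  corpus <- build_corpus(ann, onto, mondo = mondo,
                         unknown_default = config$unknown_default)
  if (!is.na(attr(corpus, "n_unmapped") %||% NA)) {
    message(sprintf("ingest: %d disease id(s) left unmapped",
                    attr(corpus, "n_unmapped")))
  }
  profile <- load_profile(config$profile)
  ic <- compute_ic(onto, corpus)

  scores <- score_all(corpus, profile, onto, ic = ic,
                      methods = config$methods, alpha = config$alpha)
  zero <- scores |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(n_zero = sum(.data$score == 0), .groups = "drop")
  message(paste(sprintf("scores: %s has %d zero-score disease(s)",
                        zero$method, zero$n_zero), collapse = "; "))

  ranking <- rank_scores(scores)
  tau <- tau_matrix(ranking)
  consensus <- aggregate_rankings(
    ranking[ranking$method %in% config$consensus_methods, ]
  )
  categories <- if (!is.null(mondo)) {
    classify_categories(consensus, mondo, k = config$k)
  }

  readr::write_tsv(as.data.frame(scores), file.path(out_dir, "scores.tsv"),
                   progress = FALSE)
  readr::write_tsv(as.data.frame(ranking), file.path(out_dir, "rankings.tsv"),
                   progress = FALSE)
  write_tau_matrix(tau, file.path(out_dir, "tau_matrix.tsv"))
  readr::write_tsv(as.data.frame(consensus),
                   file.path(out_dir, "consensus.tsv"), progress = FALSE)
  if (!is.null(categories)) {
    readr::write_tsv(as.data.frame(categories),
                     file.path(out_dir, "categories.tsv"), progress = FALSE)
  }
  write_corpus(corpus, file.path(out_dir, "corpus.tsv"))

  inputs <- purrr::compact(config[c("hp_obo", "hpoa", "profile", "mondo_obo")])
  manifest <- list(
    config = config[setdiff(names(config), "consensus_methods_internal")],
    input_md5 = purrr::map(inputs, ~ unname(tools::md5sum(.x)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(corpus = corpus, profile = profile, scores = scores,
                 ranking = ranking, tau = tau, consensus = consensus,
                 categories = categories))
}

#' One-command demo on synthetic data
#'
#' Generates a seeded synthetic ontology, annotation corpus, disease
#' ontology and query with planted diseases, writes them to `out_dir`,
#' runs the full pipeline on them and checks that the planted clone tops
#' the consensus.
#'
#' @param out_dir Directory to write inputs and results into.
#' @param seed Integer seed for the generators.
#' @param config A [synthetic_config()] (its seed is overridden by
#'   `seed`).
#' @return Invisibly, the [run_pipeline()] result list plus `answer_key`.
#' @export
run_demo <- function(out_dir, seed = 42, config = synthetic_config()) {
  config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  onto <- generate_ontology(config)
  hpoa <- generate_corpus(onto, config)
  planted <- plant_query(hpoa, onto, config)
  mondo <- generate_disease_ontology(config)

  obo_path <- file.path(out_dir, "ontology.obo")
  write_ontology_obo(onto, obo_path)
  hpoa_path <- file.path(out_dir, "corpus.hpoa")
  readr::write_lines(planted$hpoa, hpoa_path)
  profile_path <- file.path(out_dir, "query.tsv")
  write_profile(planted$profile, profile_path)
  jsonlite::write_json(planted$answer_key,
                       file.path(out_dir, "answer_key.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg <- pipeline_config(hp_obo = obo_path, hpoa = hpoa_path,
                         profile = profile_path, seed = seed)
  res <- run_pipeline(cfg, file.path(out_dir, "results"))
  top1 <- res$consensus$disease_id[res$consensus$rank == 1]
  message(sprintf("demo: consensus top-1 is %s (planted clone: %s)",
                  top1, planted$answer_key$clone_id))
  invisible(c(res, list(answer_key = planted$answer_key)))
}

#' Serialize an ontology back to OBO text
#'
#' Writes the minimal tag set ([Term] stanzas with id, name, is_a) that
#' [parse_obo()] reads; alternate ids and xrefs are emitted when present.
#'
#' @param ontology A `phen_ontology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ontology_obo <- function(ontology, path) {
  g <- ontology$graph
  lines <- c("format-version: 1.2")
  for (t in ontology$terms$term_id) {
    parents <- igraph::V(g)$name[as.integer(igraph::neighbors(g, t, mode = "out"))]
    alt <- names(ontology$alt_ids)[ontology$alt_ids == t]
    xr <- ontology$xrefs[[t]]
    lines <- c(lines, "", "[Term]", sprintf("id: %s", t),
               sprintf("name: %s",
                       ontology$terms$name[ontology$terms$term_id == t]),
               if (length(alt)) sprintf("alt_id: %s", alt),
               if (length(xr)) sprintf("xref: %s", xr),
               if (length(parents)) sprintf("is_a: %s", sort(parents)))
  }
  readr::write_lines(lines, path)
  invisible(path)
}
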