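# Rankings: turn score tables into per-method disease rankings, compare
# rankings with a top-weighted (hyperbolic) Kendall tau, aggregate them
# into an equal-weight consensus, and classify top diseases into the
# high-level categories of a disease ontology.

#' Rank diseases by score
#'
#' Stable descending sort with a deterministic tie policy: equal scores are
#' ordered by lexicographic disease id. Ranks run 1..n without gaps. When
#' the score table holds several methods, each method is ranked
#' independently.
#'
#' @param scores A `phen_scores` tibble (`disease_id`, `method`, `score`),
#'   or any tibble with `disease_id` and `score`.
#' @return A `phen_ranking` tibble: `method` (if present), `disease_id`,
#'   `score`, `rank`.
#' @export
rank_scores <- function(scores) {
  rank_one <- function(d, ...) {
    if (anyDuplicated(d$disease_id)) {
      rlang::abort(sprintf("duplicate disease id in scores: %s",
                           d$disease_id[duplicated(d$disease_id)][1]))
    }
    d <- d[order(-d$score, d$disease_id), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  }
  out <- if ("method" %in% names(scores)) {
    scores |>
      dplyr::group_by(.data$method) |>
      dplyr::group_modify(rank_one) |>
      dplyr::ungroup()
  } else {
    rank_one(scores)
  }
  class(out) <- c("phen_ranking", class(out))
  out
}

# hyperbolic rank weight: position r gets 1/(r+1)
hyperbolic_weight <- function(r) 1 / (r + 1)

wkt_one_direction <- function(r_ref, r_other) {
  n <- length(r_ref)
  w <- hyperbolic_weight(r_ref)
  W <- outer(w, w, `+`)
  sx <- sign(outer(r_ref, r_ref, `-`))
  sy <- sign(outer(r_other, r_other, `-`))
  ut <- upper.tri(W)
  num <- sum(W[ut] * sx[ut] * sy[ut])
  den <- sqrt(sum(W[ut] * sx[ut]^2) * sum(W[ut] * sy[ut]^2))
  if (den == 0) return(0)
  num / den
}

#' Weighted Kendall tau between two rankings
#'
#' Rank correlation in \[-1, 1\] where an exchange between positions `i`
#' and `j` carries weight `w(r_i) + w(r_j)` with the hyperbolic weight
#' `w(r) = 1/(r + 1)`, so disagreements near the top of the rankings count
#' far more than disagreements in the tail. Since the weights depend on
#' which ranking supplies the reference positions, the statistic is
#' computed once with each ranking as reference and the two values are
#' averaged; the normalisation makes `tau(r, r) = 1` and
#' `tau(r, reverse(r)) = -1` exactly.
#'
#' @param r1,r2 `phen_ranking` tibbles (single method each) over the same
#'   disease set.
#' @return A number in \[-1, 1\].
#' @export
weighted_kendall_tau <- function(r1, r2) {
  if ("method" %in% names(r1) && length(unique(r1$method)) > 1L ||
      "method" %in% names(r2) && length(unique(r2$method)) > 1L) {
    rlang::abort("pass one method's ranking at a time")
  }
  sd <- c(setdiff(r1$disease_id, r2$disease_id),
          setdiff(r2$disease_id, r1$disease_id))
  if (length(sd) > 0L) {
    rlang::abort(sprintf(
      "rankings cover different disease sets; symmetric difference: %s",
      paste(utils::head(sd, 5), collapse = ", ")
    ))
  }
  a <- r1$rank[order(r1$disease_id)]
  b <- r2$rank[order(r2$disease_id)]
  (wkt_one_direction(a, b) + wkt_one_direction(b, a)) / 2
}

#' Pairwise weighted-tau matrix between method rankings
#'
#' @param ranking A multi-method `phen_ranking` tibble.
#' @return A symmetric `phen_tau` matrix with unit diagonal, one row and
#'   column per method.
#' @export
tau_matrix <- function(ranking) {
  methods <- unique(ranking$method)
  parts <- lapply(methods, function(m) ranking[ranking$method == m, ])
  names(parts) <- methods
  k <- length(methods)
  tm <- diag(1, k)
  dimnames(tm) <- list(methods, methods)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      tm[i, j] <- tm[j, i] <- weighted_kendall_tau(parts[[i]], parts[[j]])
    }
  }
  class(tm) <- c("phen_tau", class(tm))
  tm
}

#' Aggregate method rankings into a consensus
#'
#' Equal-weight, score-based aggregation: within each method the scores
#' are divided by that method's maximum, the normalised scores are
#' averaged across methods, diseases are re-ranked by the mean, and the
#' aggregate scores are renormalised so the top disease has score 1.
#' A rank-based alternative (`weights = "rank"`, mean of `1/rank`) is
#' available.
#'
#' @param ranking A multi-method `phen_ranking` covering at least two
#'   methods over a shared disease set.
#' @param weights `"score"` (default) or `"rank"`.
#' @return A `phen_consensus` tibble: `disease_id`, `score` (top = 1),
#'   `rank`; methods used recorded as an attribute.
#' @export
aggregate_rankings <- function(ranking, weights = c("score", "rank")) {
  weights <- match.arg(weights)
  methods <- sort(unique(ranking$method))
  if (length(methods) < 2L) {
    rlang::abort("consensus aggregation needs at least two method rankings")
  }
  per <- ranking |>
    dplyr::group_by(.data$method) |>
    dplyr::mutate(norm = if (weights == "score") {
      if (max(.data$score) > 0) .data$score / max(.data$score) else .data$score
    } else {
      1 / .data$rank
    }) |>
    dplyr::ungroup()
  agg <- per |>
    dplyr::group_by(.data$disease_id) |>
    dplyr::summarise(score = mean(.data$norm), n_methods = dplyr::n(),
                     .groups = "drop")
  if (length(unique(agg$n_methods)) > 1L) {
    rlang::abort("method rankings cover different disease sets")
  }
  out <- rank_scores(agg[, c("disease_id", "score")])
  if (max(out$score) > 0) out$score <- out$score / max(out$score)
  attr(out, "methods_used") <- methods
  class(out) <- c("phen_consensus", setdiff(class(out), "phen_consensus"))
  out
}

#' Classify top-ranked diseases into high-level ontology categories
#'
#' For each of the top `k` consensus diseases carrying an id from the
#' disease ontology (e.g. MONDO), all paths to the root are traced and
#' every high-level category reached — the direct children of the ontology
#' root, the "main disease classes" — is counted once per disease.
#' Diseases whose ids are not ontology terms are skipped and counted
#' separately.
#'
#' @param consensus A `phen_consensus` (or any ranking) tibble.
#' @param mondo The disease `phen_ontology`.
#' @param k Number of top diseases to classify (capped at the table size
#'   with a warning).
#' @return A `phen_categories` tibble: `category_id`, `category_name`,
#'   `count`, with attributes `k` and `n_skipped`.
#' @export
classify_categories <- function(consensus, mondo, k = 50) {
  if (k > nrow(consensus)) {
    rlang::warn(sprintf("k = %d exceeds the %d ranked diseases; capping",
                        k, nrow(consensus)))
    k <- nrow(consensus)
  }
  top <- consensus[order(consensus$rank), ][seq_len(k), ]
  root_children <- igraph::V(mondo$graph)$name[
    as.integer(igraph::neighbors(mondo$graph, mondo$root, mode = "in"))
  ]
  ids <- resolve_term_ids(mondo, top$disease_id, strict = FALSE)
  skipped <- sum(is.na(ids))
  hits <- purrr::map(ids[!is.na(ids)], function(d) {
    intersect(ancestors(mondo, d), root_children)
  })
  counts <- table(factor(unlist(hits), levels = sort(root_children)))
  out <- tibble::tibble(
    category_id = names(counts),
    category_name = mondo$terms$name[match(names(counts),
                                           mondo$terms$term_id)],
    count = as.integer(counts)
  )
  attr(out, "k") <- k
  attr(out, "n_skipped") <- skipped
  class(out) <- c("phen_categories", class(out))
  out
}

#' Sensitivity of query-expansion rankings to the decay factor
#'
#' Re-scores the corpus with TF-IDF + query expansion at each value of
#' `alphas` and returns the pairwise weighted Kendall tau matrix between
#' the resulting rankings — the harness used to check that the choice of
#' decay factor does not reshuffle the top of the ranking.
#'
#' @param corpus A `phen_corpus` tibble.
#' @param profile The query `phen_profile`.
#' @param ontology A `phen_ontology`.
#' @param ic Optional `phen_ic` (computed from the corpus when `NULL`).
#' @param alphas Numeric vector of decay factors; default is the standard
#'   sweep `c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1)`.
#' @return A symmetric `phen_tau` matrix with unit diagonal, labelled by
#'   alpha.
#' @export
alpha_sensitivity <- function(corpus, profile, ontology, ic = NULL,
                              alphas = c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1)) {
  stopifnot(length(alphas) >= 1L)
  if (is.null(ic)) ic <- compute_ic(ontology, corpus)
  rankings <- purrr::map(alphas, function(a) {
    s <- score_all(corpus, profile, ontology, ic = ic,
                   methods = "tfidf_qe", alpha = a)
    s$method <- sprintf("alpha_%g", a)
    s
  })
  ranking <- rank_scores(dplyr::bind_rows(rankings))
  tm <- tau_matrix(ranking)
  # preserve the supplied alpha order
  ord <- sprintf("alpha_%g", alphas)
  tm2 <- unclass(tm)[ord, ord, drop = FALSE]
  class(tm2) <- class(tm)
  tm2
}

#' Write a tau matrix as tab-separated text with header row and column
#'
#' @param tau A `phen_tau` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tau_matrix <- function(tau, path) {
  df <- data.frame(method = rownames(tau), unclass(tau),
                   check.names = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @method tidy phen_tau
#' @export
tidy.phen_tau <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    method_a = rep(rownames(m), times = ncol(m)),
    method_b = rep(colnames(m), each = nrow(m)),
    tau = as.vector(m)
  )
}
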