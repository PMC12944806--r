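# Five phenotypic similarity measures between a query symptom profile and
# every disease in a corpus: Jaccard overlap of term sets, Resnik
# information-content similarity (pairwise average and best-match average),
# GraphIC (IC mass shared by ancestor-expanded term sets), and TF-IDF
# cosine similarity, optionally after query expansion over the ontology
# graph.

#' Jaccard index of two term sets
#'
#' `|A ∩ B| / |A ∪ B|`; duplicate entries are ignored. Two empty sets give
#' 0 (not 1), so annotation-free profiles never outrank genuine matches.
#'
#' @param a,b Character vectors of term ids.
#' @return A number in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Resnik similarity of two terms
#'
#' The information content of the most informative common ancestor of the
#' two terms (ancestor sets are self-inclusive, so `resnik_term(x, x)`
#' equals `ic(x)`).
#'
#' @param ontology A `phen_ontology`.
#' @param ic A `phen_ic` table from [compute_ic()].
#' @param x1,x2 Term ids.
#' @return Similarity in nats, `>= 0`.
#' @export
resnik_term <- function(ontology, ic, x1, x2) {
  common <- intersect(ancestors(ontology, x1), ancestors(ontology, x2))
  if (length(common) == 0L) return(0)
  icv <- ic_vector(ic)[common]
  icv <- icv[is.finite(icv)]
  if (length(icv) == 0L) return(0)
  max(icv, 0)
}

# Q x V matrix of term-pair Resnik similarities; anc is the logical
# ancestor matrix, icv a named ic vector over its columns.
resnik_pair_matrix <- function(anc, icv, qterms, vterms) {
  icm <- ifelse(is.na(icv) | !is.finite(icv), -Inf, icv)[colnames(anc)]
  Av <- anc[vterms, , drop = FALSE]
  S <- matrix(0, length(qterms), length(vterms),
              dimnames = list(qterms, vterms))
  for (i in seq_along(qterms)) {
    ic_q <- ifelse(anc[qterms[i], ], icm, -Inf)
    m <- apply(Av, 1L, function(r) suppressWarnings(max(ic_q[r])))
    m[!is.finite(m)] <- 0
    S[i, ] <- pmax(m, 0)
  }
  S
}

#' Resnik similarity of two symptom profiles
#'
#' Combines pairwise term similarities over the full grid of term pairs
#' from the two profiles. `combine = "avg"` is the plain mean over all
#' pairs; `combine = "bma"` is the best-match average — the mean of each
#' profile's best match in the other, averaged over the two directions —
#' which stops a profile with a single very specific term from dominating.
#'
#' @param ontology A `phen_ontology`.
#' @param ic A `phen_ic` table.
#' @param a,b Character vectors of term ids (non-empty).
#' @param combine `"bma"` (default) or `"avg"`.
#' @return Similarity in nats, `>= 0`; symmetric in `a` and `b`.
#' @export
resnik_profile <- function(ontology, ic, a, b, combine = c("bma", "avg")) {
  combine <- match.arg(combine)
  a <- unique(resolve_term_ids(ontology, a))
  b <- unique(resolve_term_ids(ontology, b))
  if (length(a) == 0L || length(b) == 0L) {
    rlang::abort("Resnik similarity needs two non-empty profiles")
  }
  anc <- ancestor_matrix(ontology)
  S <- resnik_pair_matrix(anc, ic_vector(ic), a, b)
  if (combine == "avg") return(mean(S))
  (mean(apply(S, 1L, max)) + mean(apply(S, 2L, max))) / 2
}

#' GraphIC similarity of two symptom profiles
#'
#' Both term sets are expanded with all ancestors of each term up to the
#' root; the similarity is the total information content of the shared
#' expanded terms divided by that of their union, giving a score in
#' \[0, 1\] that rewards overlap anywhere along the ontology paths, not
#' just at the annotated leaves.
#'
#' @inheritParams resnik_profile
#' @return A number in \[0, 1\]; 0 (with a warning) when every term in the
#'   union has zero information content.
#' @export
graphic_similarity <- function(ontology, ic, a, b) {
  a <- unique(resolve_term_ids(ontology, a))
  b <- unique(resolve_term_ids(ontology, b))
  if (length(a) == 0L || length(b) == 0L) {
    rlang::abort("GraphIC similarity needs two non-empty profiles")
  }
  a_exp <- unique(unlist(lapply(a, ancestors, ontology = ontology)))
  b_exp <- unique(unlist(lapply(b, ancestors, ontology = ontology)))
  icv <- ic_vector(ic)
  icv[is.na(icv) | !is.finite(icv)] <- 0
  num <- sum(icv[intersect(a_exp, b_exp)])
  den <- sum(icv[union(a_exp, b_exp)])
  if (den == 0) {
    rlang::warn("GraphIC denominator is 0 (no informative terms in union); returning 0")
    return(0)
  }
  num / den
}

#' Expand a query profile over the ontology graph
#'
#' Every ontology term `y` receives an artificial frequency
#' `f_y = f_x * alpha^d(x, y)`, where `x` is the query (seed) term closest
#' to `y` in undirected graph distance `d` and `alpha` in \[0, 1\] is the
#' decay factor. Seed terms keep their own frequency (`d = 0`; this holds
#' for `alpha = 0` too, under the `0^0 = 1` convention, where expansion
#' degenerates to the seed set). When two seeds are equidistant from `y`
#' the one yielding the larger expanded frequency wins, which keeps the
#' result independent of seed order. Terms disconnected from every seed
#' are left out.
#'
#' The expansion runs over the whole supplied ontology; pass an ontology
#' already restricted to the phenotypic-abnormality branch (see
#' [restrict_to_subtree()]) so that only terms the corpus can match are
#' added.
#'
#' @param profile A `phen_profile` (or any tibble with `term_id` and
#'   `frequency`).
#' @param ontology A `phen_ontology` containing every query term.
#' @param alpha Decay factor in \[0, 1\]; 0.5 by default, the sweep preset
#'   used for sensitivity analysis is `c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1)`.
#' @return A `phen_expanded` tibble: `term_id`, `frequency`, `seed_term`,
#'   `distance`, with `alpha` as an attribute.
#' @export
expand_query <- function(profile, ontology, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  seeds <- resolve_term_ids(ontology, profile$term_id)
  f_seed <- profile$frequency
  d <- term_distance_matrix(ontology, seeds)   # seeds x all terms
  # candidate frequency from each seed; 0^0 = 1 keeps seeds at their own f
  fcand <- f_seed * alpha^d
  fcand[!is.finite(d)] <- -Inf
  dmin <- apply(d, 2L, min)
  best <- integer(ncol(d))
  for (j in seq_len(ncol(d))) {
    at_min <- which(d[, j] == dmin[j])
    best[j] <- at_min[which.max(fcand[at_min, j])]
  }
  out <- tibble::tibble(
    term_id = colnames(d),
    frequency = unname(fcand[cbind(best, seq_len(ncol(d)))]),
    seed_term = unname(seeds[best]),
    distance = unname(dmin)
  )
  out <- out[is.finite(out$distance), , drop = FALSE]
  out$frequency[out$distance == 0] <-
    f_seed[match(out$seed_term[out$distance == 0], seeds)]
  out <- dplyr::arrange(out, .data$term_id)
  attr(out, "alpha") <- alpha
  class(out) <- c("phen_expanded", class(out))
  out
}

#' TF-IDF vectors for a corpus and a query
#'
#' Treats each disease as a document and its annotated terms as words.
#' The term weight is `tf * idf` with `tf` the stored annotation frequency
#' (`tf = "frequency"`, the default — symptom importance enters through how
#' often patients show it) or a 0/1 indicator (`tf = "binary"`), and
#' `idf = log((1 + N) / (1 + df)) + 1`, the smoothed inverse document
#' frequency (`N` diseases in the corpus, `df` diseases directly annotated
#' to the term). The smoothing keeps idf strictly positive, so query terms
#' absent from the corpus vocabulary still contribute. The query (plain or
#' expanded) is vectorised in the same term space.
#'
#' @param corpus A `phen_corpus` tibble.
#' @param query A `phen_profile` or `phen_expanded` tibble.
#' @param tf `"frequency"` or `"binary"`.
#' @return A `phen_tfidf` list: `disease_matrix` (diseases x vocabulary),
#'   `query` (named vector), `idf` (named vector).
#' @export
tfidf_vectors <- function(corpus, query, tf = c("frequency", "binary")) {
  tf <- match.arg(tf)
  if (nrow(corpus) == 0L) rlang::abort("corpus is empty")
  vocab <- sort(union(unique(corpus$term_id), unique(query$term_id)))
  n <- length(unique(corpus$disease_id))
  df <- table(factor(unique(corpus[, c("disease_id", "term_id")])$term_id,
                     levels = vocab))
  idf <- log((1 + n) / (1 + as.numeric(df))) + 1
  names(idf) <- vocab

  diseases <- sort(unique(corpus$disease_id))
  m <- matrix(0, length(diseases), length(vocab),
              dimnames = list(diseases, vocab))
  tfval <- if (tf == "frequency") corpus$frequency else 1
  m[cbind(corpus$disease_id, corpus$term_id)] <- tfval
  m <- sweep(m, 2L, idf, `*`)

  q <- stats::setNames(numeric(length(vocab)), vocab)
  qtf <- if (tf == "frequency") query$frequency else 1
  q[query$term_id] <- qtf
  q <- q * idf

  structure(list(disease_matrix = m, query = q, idf = idf),
            class = "phen_tfidf")
}

#' Cosine similarity of two weight vectors
#'
#' @param u,v Numeric vectors of equal length (or named vectors over the
#'   same vocabulary).
#' @return `dot(u, v) / (|u| |v|)` in \[0, 1\] for non-negative weights;
#'   0 when either norm is 0.
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

phen_methods <- c("jaccard", "resnik_bma", "resnik_avg", "graphic",
                  "tfidf", "tfidf_qe")

#' Score every corpus disease against a query profile
#'
#' Computes the similarity between the query and each disease under the
#' requested methods: `jaccard`, `resnik_bma` (best-match average, the
#' headline Resnik variant), `resnik_avg`, `graphic`, `tfidf` (cosine over
#' TF-IDF vectors) and `tfidf_qe` (the same after expanding the query over
#' the ontology with decay `alpha`). All methods are deterministic;
#' frequencies influence only the TF-IDF family, the set-based and
#' IC-based measures use the term sets alone.
#'
#' @param corpus A `phen_corpus` tibble.
#' @param profile A `phen_profile` tibble (the query).
#' @param ontology A `phen_ontology` covering corpus and query terms.
#' @param ic Optional `phen_ic`; computed from `corpus` when `NULL`.
#' @param methods Subset of
#'   `c("jaccard", "resnik_bma", "resnik_avg", "graphic", "tfidf", "tfidf_qe")`;
#'   the default is the five headline measures.
#' @param alpha Query-expansion decay factor (used by `tfidf_qe` only).
#' @param tf TF-IDF term-frequency mode, see [tfidf_vectors()].
#' @return A `phen_scores` tibble: `disease_id`, `method`, `score`, one
#'   row per disease and method.
#' @export
score_all <- function(corpus, profile, ontology, ic = NULL,
                      methods = c("jaccard", "resnik_bma", "graphic",
                                  "tfidf", "tfidf_qe"),
                      alpha = 0.5, tf = "frequency") {
  unknown <- setdiff(methods, phen_methods)
  if (length(unknown) > 0L) {
    rlang::abort(sprintf("unknown method(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(ic)) ic <- compute_ic(ontology, corpus)
  corpus$term_id <- resolve_term_ids(ontology, corpus$term_id)
  qterms <- unique(resolve_term_ids(ontology, profile$term_id))

  by_disease <- split(corpus$term_id, corpus$disease_id)
  diseases <- names(by_disease)
  res <- list()

  if ("jaccard" %in% methods) {
    res$jaccard <- purrr::map_dbl(by_disease, jaccard_similarity, a = qterms)
  }

  if (any(c("resnik_bma", "resnik_avg", "graphic") %in% methods)) {
    anc <- ancestor_matrix(ontology)
    icv <- ic_vector(ic)
  }
  if (any(c("resnik_bma", "resnik_avg") %in% methods)) {
    S <- resnik_pair_matrix(anc, icv, qterms, colnames(anc))
    if ("resnik_bma" %in% methods) {
      res$resnik_bma <- purrr::map_dbl(by_disease, function(tb) {
        sub <- S[, unique(tb), drop = FALSE]
        (mean(apply(sub, 1L, max)) + mean(apply(sub, 2L, max))) / 2
      })
    }
    if ("resnik_avg" %in% methods) {
      res$resnik_avg <- purrr::map_dbl(by_disease, function(tb) {
        mean(S[, unique(tb), drop = FALSE])
      })
    }
  }
  if ("graphic" %in% methods) {
    ics <- icv
    ics[is.na(ics) | !is.finite(ics)] <- 0
    q_exp <- colSums(anc[qterms, , drop = FALSE]) > 0
    res$graphic <- purrr::map_dbl(by_disease, function(tb) {
      b_exp <- colSums(anc[unique(tb), , drop = FALSE]) > 0
      den <- sum(ics[q_exp | b_exp])
      if (den == 0) return(0)
      sum(ics[q_exp & b_exp]) / den
    })
  }

  if ("tfidf" %in% methods) {
    vec <- tfidf_vectors(corpus, profile, tf = tf)
    res$tfidf <- apply(vec$disease_matrix, 1L, cosine_similarity,
                       v = vec$query)
  }
  if ("tfidf_qe" %in% methods) {
    expanded <- expand_query(profile, ontology, alpha = alpha)
    vec <- tfidf_vectors(corpus, expanded, tf = tf)
    res$tfidf_qe <- apply(vec$disease_matrix, 1L, cosine_similarity,
                          v = vec$query)
  }

  out <- purrr::imap_dfr(res[intersect(phen_methods, names(res))],
    function(v, m) {
      tibble::tibble(disease_id = diseases, method = m,
                     score = unname(v[diseases]))
    })
  attr(out, "alpha") <- alpha
  class(out) <- c("phen_scores", class(out))
  out
}
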