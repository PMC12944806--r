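# Ontology: rooted DAG of phenotype terms linked by is_a edges, parsed from
# OBO flat files. Traversal (reachability, undirected shortest paths) is
# backed by igraph; all user-facing accessors speak term identifiers.

new_ontology <- function(terms, graph, root, alt_ids, xrefs) {
  structure(
    list(terms = terms, graph = graph, root = root,
         alt_ids = alt_ids, xrefs = xrefs),
    class = "phen_ontology"
  )
}

#' Parse an OBO ontology file into a rooted DAG
#'
#' Reads the OBO 1.2/1.4 flat-file dialect used by the Human Phenotype
#' Ontology and MONDO. Only `[Term]` stanzas are interpreted, and of those
#' only the tags `id`, `name`, `is_a`, `alt_id`, `xref` and `is_obsolete`;
#' other relationship types, logical definitions and imports are ignored.
#' Obsolete terms are dropped together with their edges. Alternate ids are
#' resolved at parse time, so every downstream function sees primary ids
#' only.
#'
#' @param file Path to an OBO file, or a character vector of OBO lines
#'   (anything containing a newline or a `[Term]` stanza is treated as
#'   literal text).
#' @return A `phen_ontology` object: a rooted directed acyclic graph whose
#'   edges point from each term to its parents. Access the term table with
#'   [tidy()], a one-row summary with [glance()].
#' @examples
#' obo <- c("[Term]", "id: T:1", "name: root",
#'          "[Term]", "id: T:2", "name: child", "is_a: T:1")
#' onto <- parse_obo(obo)
#' ancestors(onto, "T:2")
#' @export
parse_obo <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) &&
               !grepl("^\\[", file) && file.exists(file)) {
    readr::read_lines(file)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\\s+$", "", lines)

  # stanza boundaries: any [...] header line
  hdr <- grep("^\\[.*\\]$", lines)
  if (length(hdr) == 0L) {
    rlang::abort("no OBO stanzas found in input")
  }
  is_term <- lines[hdr] == "[Term]"
  starts <- hdr[is_term]
  ends <- c(hdr[-1L], length(lines) + 1L)[match(starts, hdr)] - 1L

  parse_stanza <- function(from, to) {
    body <- lines[seq(from + 1L, length.out = max(0L, to - from))]
    body <- body[nzchar(body)]
    tag <- sub(":.*$", "", body)
    val <- sub("^[^:]+:\\s*", "", body)
    val <- sub("\\s*!.*$", "", val)  # strip trailing comments
    id <- val[tag == "id"][1]
    if (is.na(id) || !nzchar(id)) {
      rlang::abort(sprintf("[Term] stanza at line %d has no id", from))
    }
    list(
      id = id,
      name = val[tag == "name"][1] %||% id,
      is_a = val[tag == "is_a"],
      alt_id = val[tag == "alt_id"],
      xref = val[tag == "xref"],
      obsolete = any(tag == "is_obsolete" & grepl("true", val))
    )
  }
  stanzas <- purrr::map2(starts, ends, parse_stanza)

  obsolete <- purrr::map_lgl(stanzas, "obsolete")
  kept <- stanzas[!obsolete]
  if (length(kept) == 0L) rlang::abort("ontology contains no usable terms")
  ids <- purrr::map_chr(kept, "id")
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicate term id: %s", ids[duplicated(ids)][1]))
  }

  terms <- tibble::tibble(
    term_id = ids,
    name = purrr::map_chr(kept, "name")
  )
  edges <- purrr::map_dfr(kept, function(s) {
    parents <- intersect(s$is_a, ids)  # edges into obsolete/foreign ids dropped
    tibble::tibble(child = rep(s$id, length(parents)), parent = parents)
  })

  graph <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(graph, mode = "strong")
  if (any(comp$csize > 1L)) {
    bad <- names(comp$membership)[comp$membership == which(comp$csize > 1L)[1]][1]
    rlang::abort(sprintf("is_a cycle detected involving term %s", bad))
  }

  roots <- ids[igraph::degree(graph, mode = "out") == 0L]
  if (length(roots) != 1L) {
    rlang::abort(sprintf(
      "ontology must have exactly one root; found %d (%s)",
      length(roots), paste(utils::head(roots, 3), collapse = ", ")
    ))
  }

  alt <- purrr::map(kept, "alt_id")
  alt_ids <- stats::setNames(rep(ids, lengths(alt)), unlist(alt))
  xrefs <- stats::setNames(purrr::map(kept, "xref"), ids)
  xrefs <- xrefs[lengths(xrefs) > 0L]

  new_ontology(terms, graph, roots, alt_ids, xrefs)
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0L || is.na(x[1])) y else x

#' @export
print.phen_ontology <- function(x, ...) {
  cat(sprintf(
    "<phen_ontology> %d terms, %d is_a edges, root %s\n",
    nrow(x$terms), igraph::ecount(x$graph), x$root
  ))
  invisible(x)
}

term_ids <- function(ontology) ontology$terms$term_id

#' Resolve term identifiers to primary ids
#'
#' Maps alternate ids recorded at parse time onto their primary term id;
#' ids already primary pass through unchanged.
#'
#' @param ontology A `phen_ontology`.
#' @param ids Character vector of term ids.
#' @param strict Error on ids unknown even after alt-id resolution.
#' @return Character vector of primary ids (`NA` for unknowns when
#'   `strict = FALSE`).
#' @export
resolve_term_ids <- function(ontology, ids, strict = TRUE) {
  out <- ids
  is_alt <- out %in% names(ontology$alt_ids)
  out[is_alt] <- unname(ontology$alt_ids[out[is_alt]])
  unknown <- !(out %in% term_ids(ontology))
  if (any(unknown)) {
    if (strict) {
      rlang::abort(sprintf(
        "unknown term id(s): %s",
        paste(unique(ids[unknown]), collapse = ", ")
      ))
    }
    out[unknown] <- NA_character_
  }
  out
}

#' Ancestors of a term
#'
#' All terms reachable from `x` by following is_a edges towards the root.
#' The set is self-inclusive: `x` is one of its own ancestors, so that
#' ancestor-expanded profiles always contain the original terms.
#'
#' @param ontology A `phen_ontology`.
#' @param x A single term id (alt ids accepted).
#' @return Character vector of term ids, including `x` and the root.
#' @export
ancestors <- function(ontology, x) {
  x <- resolve_term_ids(ontology, x)
  stopifnot(length(x) == 1L)
  v <- igraph::subcomponent(ontology$graph, x, mode = "out")
  igraph::V(ontology$graph)$name[as.integer(v)]
}

# T x T logical matrix: [i, j] TRUE iff term j is an ancestor of term i
# (self-inclusive). Dense, so only for the modest ontologies the pipeline
# actually scores against; row/col names are term ids.
ancestor_matrix <- function(ontology) {
  d <- igraph::distances(ontology$graph, mode = "out")
  m <- is.finite(d)
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

#' Undirected shortest-path distance between two terms
#'
#' Edge count of the shortest path linking `x` and `y` when is_a edges are
#' traversed in either direction, i.e. paths may climb towards the root and
#' descend again. This is the graph distance used by query expansion.
#'
#' @param ontology A `phen_ontology`.
#' @param x,y Term ids.
#' @return A non-negative number of edges; `Inf` when the terms are
#'   disconnected (possible only in non-rooted synthetic graphs).
#' @export
term_distance <- function(ontology, x, y) {
  x <- resolve_term_ids(ontology, x)
  y <- resolve_term_ids(ontology, y)
  as.numeric(igraph::distances(ontology$graph, v = x, to = y, mode = "all"))
}

# distances from several source terms to all ontology terms (undirected);
# rows = sources, columns = every term
term_distance_matrix <- function(ontology, from) {
  from <- resolve_term_ids(ontology, from)
  igraph::distances(ontology$graph, v = from, mode = "all")
}

#' Restrict an ontology to the subtree under one term
#'
#' Induced sub-DAG on the descendants of `subroot` (self-inclusive);
#' `subroot` becomes the root of the result. Used to cut an ontology down
#' to its phenotypic-abnormality branch before scoring.
#'
#' @param ontology A `phen_ontology`.
#' @param subroot Term id of the new root.
#' @return A `phen_ontology`.
#' @export
restrict_to_subtree <- function(ontology, subroot) {
  subroot <- resolve_term_ids(ontology, subroot)
  keep <- igraph::subcomponent(ontology$graph, subroot, mode = "in")
  keep_ids <- igraph::V(ontology$graph)$name[as.integer(keep)]
  graph <- igraph::induced_subgraph(ontology$graph, keep)
  terms <- dplyr::filter(ontology$terms, .data$term_id %in% keep_ids)
  alt <- ontology$alt_ids[ontology$alt_ids %in% keep_ids]
  xrefs <- ontology$xrefs[names(ontology$xrefs) %in% keep_ids]
  new_ontology(terms, graph, subroot, alt, xrefs)
}

#' Information content of every term over a disease corpus
#'
#' The annotation probability p(x) of a term is the fraction of corpus
#' diseases annotated to x or to any of its descendants (implicit
#' propagation: an annotation to a term counts for all its ancestors, the
#' standard Resnik convention). Information content is `ic = -log(p)` in
#' nats, so the root of a fully annotated corpus has ic 0 and rarer,
#' more specific terms have higher ic.
#'
#' Terms never reached by any annotation would have p = 0; under
#' `smoothing = "add_one"` (default) they get `p = 1/(corpus_size + 1)` so
#' their ic stays finite, and under `"exclude"` their ic is `NA`.
#'
#' @param ontology A `phen_ontology` covering every annotated term.
#' @param corpus A disease corpus tibble as from [build_corpus()]
#'   (columns `disease_id`, `term_id`, at least).
#' @param smoothing `"add_one"` or `"exclude"`; affects zero-count terms
#'   only.
#' @return A `phen_ic` tibble with columns `term_id`, `n_diseases`
#'   (propagated count), `p`, `ic`, carrying the corpus size as an
#'   attribute.
#' @export
compute_ic <- function(ontology, corpus, smoothing = c("add_one", "exclude")) {
  smoothing <- match.arg(smoothing)
  if (nrow(corpus) == 0L) rlang::abort("corpus is empty; cannot compute IC")
  corpus$term_id <- resolve_term_ids(ontology, corpus$term_id)

  anc <- ancestor_matrix(ontology)
  terms <- colnames(anc)
  diseases <- unique(corpus$disease_id)

  direct <- matrix(FALSE, length(diseases), length(terms),
                   dimnames = list(diseases, terms))
  direct[cbind(corpus$disease_id, corpus$term_id)] <- TRUE
  # disease counts for a term t = diseases hitting t or any descendant,
  # i.e. diseases with a direct term whose ancestor set contains t
  counts <- colSums((direct %*% anc) > 0)

  n <- length(diseases)
  p <- counts / n
  if (smoothing == "add_one") {
    p[counts == 0L] <- 1 / (n + 1)
  } else {
    p[counts == 0L] <- NA_real_
  }
  out <- tibble::tibble(
    term_id = terms,
    n_diseases = as.integer(counts),
    p = unname(p),
    ic = -log(unname(p))
  )
  attr(out, "corpus_size") <- n
  class(out) <- c("phen_ic", class(out))
  out
}

# named ic lookup vector from a phen_ic table (NA -> 0 contribution guarded
# by callers)
ic_vector <- function(ic_table) {
  stats::setNames(ic_table$ic, ic_table$term_id)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy phen_ontology
#' @export
tidy.phen_ontology <- function(x, ...) {
  deg <- igraph::degree(x$graph, mode = "out")
  dplyr::mutate(x$terms,
    n_parents = as.integer(deg[.data$term_id]),
    depth = as.integer(igraph::distances(
      x$graph, to = x$root, mode = "out"
    )[.data$term_id, 1])
  )
}

#' @method glance phen_ontology
#' @export
glance.phen_ontology <- function(x, ...) {
  depths <- igraph::distances(x$graph, to = x$root, mode = "out")[, 1]
  tibble::tibble(
    n_terms = nrow(x$terms),
    n_edges = igraph::ecount(x$graph),
    root = x$root,
    max_depth = as.integer(max(depths[is.finite(depths)]))
  )
}

#' Write a JSON summary of an ontology
#'
#' @param ontology A `phen_ontology`.
#' @param path Output path; the summary (term count, edge count, root,
#'   depth) is written as a single JSON object.
#' @return `path`, invisibly.
#' @export
write_ontology_summary <- function(ontology, path) {
  jsonlite::write_json(as.list(glance(ontology)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
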