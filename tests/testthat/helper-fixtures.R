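# Shared fixtures and independent brute-force oracles. The oracles use only
# primitive loops over edge lists so they never share code paths with the
# implementations they check.

muscle_tone_ontology <- function() {
  parse_obo(system.file("extdata", "muscle_tone.obo", package = "phenonet"))
}

# edge list (child, parent) of an ontology, extracted once for the oracles
edge_list <- function(ontology) {
  e <- igraph::as_data_frame(ontology$graph, what = "edges")
  names(e) <- c("child", "parent")
  e
}

# naive ancestors by repeated expansion over the parent map
naive_ancestors <- function(ontology, x) {
  e <- edge_list(ontology)
  acc <- x
  repeat {
    nxt <- unique(c(acc, e$parent[e$child %in% acc]))
    if (length(nxt) == length(acc)) return(sort(acc))
    acc <- nxt
  }
}

# breadth-first search over undirected edges; returns edge count or Inf
naive_bfs_distance <- function(ontology, x, y) {
  e <- edge_list(ontology)
  if (x == y) return(0)
  frontier <- x
  seen <- x
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nbr <- unique(c(e$parent[e$child %in% frontier],
                    e$child[e$parent %in% frontier]))
    nbr <- setdiff(nbr, seen)
    if (y %in% nbr) return(d)
    seen <- c(seen, nbr)
    frontier <- nbr
  }
  Inf
}

naive_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- sum(a %in% b)
  uni <- length(a) + length(b) - inter
  if (uni == 0) 0 else inter / uni
}

# exhaustive max over the ancestor-set intersection, ancestors from the
# naive closure above
naive_resnik_term <- function(ontology, ic, x1, x2) {
  common <- intersect(naive_ancestors(ontology, x1),
                      naive_ancestors(ontology, x2))
  best <- 0
  for (t in common) {
    v <- ic$ic[ic$term_id == t]
    if (length(v) == 1 && is.finite(v) && v > best) best <- v
  }
  best
}

# double-loop weighted Kendall tau: additive hyperbolic weights, exchange
# between i and j weighted w(r_i) + w(r_j), symmetrised over which ranking
# supplies the reference ranks
naive_weighted_tau <- function(ra, rb) {
  one <- function(ref, oth) {
    n <- length(ref)
    num <- 0; wa <- 0; wb <- 0
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        w <- 1 / (ref[i] + 1) + 1 / (ref[j] + 1)
        sa <- sign(ref[i] - ref[j]); sb <- sign(oth[i] - oth[j])
        num <- num + w * sa * sb
        wa <- wa + w * sa^2
        wb <- wb + w * sb^2
      }
    }
    if (wa == 0 || wb == 0) 0 else num / sqrt(wa * wb)
  }
  (one(ra, rb) + one(rb, ra)) / 2
}

# all permutations of 1..n, one per row
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
  dimnames(out) <- NULL
  out
}

ranking_from_ranks <- function(ids, ranks) {
  tibble::tibble(disease_id = ids, score = -ranks, rank = ranks)
}

# tiny hand-rolled HPOA text for corpus tests
toy_hpoa <- function(rows) {
  c(paste(c("database_id", "disease_name", "qualifier", "hpo_id",
            "reference", "evidence", "onset", "frequency", "sex",
            "modifier", "aspect", "biocuration"), collapse = "\t"),
    rows)
}

toy_hpoa_row <- function(id, term, freq = "", aspect = "P", qualifier = "",
                         name = "toy disease") {
  paste(id, name, qualifier, term, "PMID:1", "TAS", "", freq, "", "",
        aspect, "CUR[2026]", sep = "\t")
}

# small diamond ontology used across modules:
# root <- a <- {b, c} <- d   (d has two parents)
diamond_ontology <- function() {
  parse_obo(c(
    "[Term]", "id: D:0", "name: root",
    "[Term]", "id: D:1", "name: a", "is_a: D:0",
    "[Term]", "id: D:2", "name: b", "is_a: D:1",
    "[Term]", "id: D:3", "name: c", "is_a: D:1",
    "[Term]", "id: D:4", "name: d", "is_a: D:2", "is_a: D:3"
  ))
}
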