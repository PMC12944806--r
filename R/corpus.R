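# Disease-phenotype annotation corpus: read the HPOA tab-separated dialect,
# keep phenotypic-abnormality annotations, unify disease identifiers through
# MONDO cross-references, and collapse heterogeneous frequency annotations
# (fractions, percentages, frequency-class terms, missing) to one frequency
# per disease-term pair.

#' Frequency-class terms and the patient-percentage intervals they encode
#'
#' The standard HPO frequency classes: each class term stands for an
#' interval of the fraction of patients exhibiting a symptom. `Occasional`,
#' for instance, covers 5--29% of patients.
#'
#' @format A tibble with columns `term_id`, `label`, `lo`, `hi`
#'   (bounds as probabilities in \[0, 1\]).
#' @export
hpo_frequency_classes <- tibble::tibble(
  term_id = c("HP:0040280", "HP:0040281", "HP:0040282",
              "HP:0040283", "HP:0040284", "HP:0040285"),
  label   = c("Obligate", "Very frequent", "Frequent",
              "Occasional", "Very rare", "Excluded"),
  lo      = c(1, 0.80, 0.30, 0.05, 0.01, 0),
  hi      = c(1, 0.99, 0.79, 0.29, 0.04, 0)
)

hpoa_required_cols <- c("database_id", "hpo_id", "frequency", "aspect")

#' Read a disease-phenotype annotation table in the HPOA dialect
#'
#' Parses the tab-separated `phenotype.hpoa` format: leading `#` comment
#' lines are skipped, the header row names the columns, and each data row
#' annotates one disease (`database_id`, e.g. an OMIM/ORPHA/DECIPHER id)
#' with one phenotype term (`hpo_id`), an optional frequency cell and an
#' aspect code. Evidence, onset, sex, modifier and biocuration columns are
#' carried through untouched but unused.
#'
#' @param file Path to an HPOA file, or a character vector of its lines.
#' @return A tibble of raw annotations with at least `database_id`,
#'   `hpo_id`, `frequency`, `aspect` and, when present, `qualifier` and
#'   `disease_name`.
#' @export
parse_hpoa <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readr::read_lines(file)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) rlang::abort("HPOA input has no header row")
  tbl <- readr::read_tsv(
    I(paste(lines, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  names(tbl) <- tolower(names(tbl))
  if ("disease_name" %in% names(tbl) == FALSE && "disease-name" %in% names(tbl)) {
    names(tbl)[names(tbl) == "disease-name"] <- "disease_name"
  }
  missing <- setdiff(hpoa_required_cols, names(tbl))
  if (length(missing) > 0L) {
    rlang::abort(sprintf(
      "HPOA input is missing mandatory column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  tbl$frequency[is.na(tbl$frequency) | tbl$frequency == ""] <- NA_character_
  malformed <- !is.na(tbl$frequency) & !frequency_parses(tbl$frequency)
  if (any(malformed)) {
    rlang::warn(sprintf(
      "%d annotation(s) had unparseable frequency cells; kept with frequency absent",
      sum(malformed)
    ))
    tbl$frequency[malformed] <- NA_character_
  }
  tbl
}

frequency_parses <- function(x) {
  grepl("^\\s*\\d+\\s*/\\s*\\d+\\s*$", x) |
    grepl("^\\s*\\d+(\\.\\d+)?\\s*%\\s*$", x) |
    x %in% hpo_frequency_classes$term_id
}

#' Keep phenotypic-abnormality annotations only
#'
#' Drops annotations that describe modes of inheritance, clinical course or
#' other non-symptom aspects. Two filters are applied together: the aspect
#' column must mark a phenotypic abnormality (`"P"`), and the term must lie
#' inside the phenotypic-abnormality subtree of the ontology. `NOT`-qualified
#' (explicitly absent) annotations are dropped as well. Dropped counts are
#' recorded as attributes.
#'
#' @param annotations Raw annotation tibble from [parse_hpoa()].
#' @param ontology The phenotype `phen_ontology` (already restricted to the
#'   phenotypic-abnormality branch where applicable).
#' @param phenotypic_aspect Aspect code marking phenotypic abnormalities.
#' @return The filtered annotation tibble, with attributes
#'   `n_dropped_aspect`, `n_dropped_subtree`, `n_dropped_not`.
#' @export
filter_phenotypic <- function(annotations, ontology, phenotypic_aspect = "P") {
  n0 <- nrow(annotations)
  not_q <- if ("qualifier" %in% names(annotations)) {
    !is.na(annotations$qualifier) & annotations$qualifier == "NOT"
  } else rep(FALSE, n0)
  keep_aspect <- annotations$aspect %in% phenotypic_aspect
  resolved <- resolve_term_ids(ontology, annotations$hpo_id, strict = FALSE)
  keep_subtree <- !is.na(resolved)
  out <- annotations[keep_aspect & keep_subtree & !not_q, , drop = FALSE]
  out$hpo_id <- resolved[keep_aspect & keep_subtree & !not_q]
  attr(out, "n_dropped_aspect") <- sum(!keep_aspect)
  attr(out, "n_dropped_subtree") <- sum(keep_aspect & !keep_subtree)
  attr(out, "n_dropped_not") <- sum(not_q & keep_aspect & keep_subtree)
  out
}

#' Normalise one raw frequency annotation to a probability
#'
#' The four HPOA frequency formats become a single `value` in \[0, 1\]:
#' a fraction `n/d` keeps its denominator as an evidence weight; a
#' percentage becomes a weightless point value; a frequency-class term maps
#' to its percentage interval with the midpoint as value; a missing cell
#' takes `unknown_default` — 0.5 by default, the mean of a uniform prior
#' over \[0, 1\], with 0.01 ("very rare") and 1.0 ("obligate") as the
#' extreme presets of the sensitivity analysis.
#'
#' @param frequency Character vector of raw frequency cells (`NA` for
#'   absent).
#' @param unknown_default Value assigned when the frequency is absent.
#' @return A tibble with one row per input: `value`, `weight` (fraction
#'   denominator or `NA`), `lo`, `hi` (interval bounds, `NA` unless the
#'   input was a class term).
#' @export
resolve_frequency <- function(frequency, unknown_default = 0.5) {
  stopifnot(unknown_default >= 0, unknown_default <= 1)
  out <- tibble::tibble(
    value = rep(NA_real_, length(frequency)),
    weight = NA_real_, lo = NA_real_, hi = NA_real_
  )
  absent <- is.na(frequency) | !nzchar(frequency)
  out$value[absent] <- unknown_default

  is_frac <- !absent & grepl("^\\s*\\d+\\s*/\\s*\\d+\\s*$", frequency)
  if (any(is_frac)) {
    num <- as.numeric(sub("/.*$", "", frequency[is_frac]))
    den <- as.numeric(sub("^[^/]*/", "", frequency[is_frac]))
    if (any(den == 0) || any(num > den)) {
      rlang::abort("fraction frequency with zero denominator or numerator > denominator")
    }
    out$value[is_frac] <- num / den
    out$weight[is_frac] <- den
  }

  is_pct <- !absent & grepl("^\\s*\\d+(\\.\\d+)?\\s*%\\s*$", frequency)
  if (any(is_pct)) {
    q <- as.numeric(sub("%.*$", "", frequency[is_pct]))
    if (any(q > 100)) rlang::abort("percentage frequency above 100%")
    out$value[is_pct] <- q / 100
  }

  is_class <- !absent & !is_frac & !is_pct
  if (any(is_class)) {
    idx <- match(frequency[is_class], hpo_frequency_classes$term_id)
    if (anyNA(idx)) {
      rlang::abort(sprintf(
        "unknown frequency-class term: %s",
        frequency[is_class][is.na(idx)][1]
      ))
    }
    out$lo[is_class] <- hpo_frequency_classes$lo[idx]
    out$hi[is_class] <- hpo_frequency_classes$hi[idx]
    out$value[is_class] <- (out$lo[is_class] + out$hi[is_class]) / 2
  }
  out
}

#' Merge conflicting frequency values for one disease-term pair
#'
#' Duplicate annotations (the same disease-term pair reported by several
#' source ontologies) are collapsed by three rules, in order:
#' \enumerate{
#'   \item all values are fractions: weighted mean with the denominators as
#'     weights, pooling the original samples;
#'   \item any value carries an interval (frequency class): the midpoint of
#'     the smallest interval compatible with every value — the intersection
#'     of all intervals when non-empty, otherwise the hull spanning them,
#'     point values counting as degenerate intervals;
#'   \item otherwise: plain arithmetic mean.
#' }
#'
#' @param values A tibble of resolved frequency rows ([resolve_frequency()]
#'   output) for a single disease-term pair.
#' @return A single-row tibble in the same shape.
#' @export
merge_duplicates <- function(values) {
  if (nrow(values) == 0L) rlang::abort("merge_duplicates needs at least one value")
  if (nrow(values) == 1L) return(values)
  if (all(!is.na(values$weight))) {
    v <- sum(values$value * values$weight) / sum(values$weight)
    return(tibble::tibble(value = v, weight = sum(values$weight),
                          lo = NA_real_, hi = NA_real_))
  }
  if (any(!is.na(values$lo))) {
    lo <- ifelse(is.na(values$lo), values$value, values$lo)
    hi <- ifelse(is.na(values$hi), values$value, values$hi)
    ilo <- max(lo); ihi <- min(hi)
    if (ilo > ihi) {      # disjoint: smallest interval containing all
      ilo <- min(lo); ihi <- max(hi)
    }
    return(tibble::tibble(value = (ilo + ihi) / 2, weight = NA_real_,
                          lo = ilo, hi = ihi))
  }
  tibble::tibble(value = mean(values$value), weight = NA_real_,
                 lo = NA_real_, hi = NA_real_)
}

#' Map source disease identifiers to MONDO
#'
#' A source id (OMIM/ORPHA/DECIPHER) maps to the MONDO term whose xref list
#' contains it. Ids matching no xref are returned unchanged and flagged; an
#' id claimed by several MONDO terms resolves deterministically to the
#' lexicographically smallest one, with a warning.
#'
#' @param disease_ids Character vector of source ids.
#' @param mondo A `phen_ontology` parsed with xrefs retained.
#' @return A tibble `disease_id`, `unified_id`, `mapped`.
#' @export
map_to_mondo <- function(disease_ids, mondo) {
  xr <- mondo$xrefs
  lookup <- tibble::tibble(
    xref = unlist(xr, use.names = FALSE),
    mondo_id = rep(names(xr), lengths(xr))
  )
  lookup <- dplyr::summarise(
    dplyr::group_by(lookup, .data$xref),
    n_hits = dplyr::n(),
    mondo_id = min(.data$mondo_id),
    .groups = "drop"
  )
  hit <- match(disease_ids, lookup$xref)
  n_hits <- ifelse(is.na(hit), 0L, lookup$n_hits[hit])
  multi_ids <- unique(disease_ids[n_hits > 1])
  if (length(multi_ids) > 0L) {
    rlang::warn(sprintf(
      "%d disease id(s) matched multiple MONDO terms; smallest id chosen (e.g. %s)",
      length(multi_ids), multi_ids[1]
    ))
  }
  tibble::tibble(
    disease_id = disease_ids,
    unified_id = ifelse(is.na(hit), disease_ids, lookup$mondo_id[hit]),
    mapped = !is.na(hit)
  )
}

#' Build a disease corpus from filtered annotations
#'
#' Groups annotations by unified disease id, resolves every frequency cell,
#' and collapses duplicate disease-term pairs with [merge_duplicates()].
#' When a MONDO ontology is supplied, identifier unification happens before
#' duplicate resolution, so the same disease annotated under several source
#' ontologies is merged into one profile (its annotations are unioned
#' first, then deduplicated). Diseases left with no annotations are
#' excluded and counted.
#'
#' @param annotations Filtered annotation tibble ([filter_phenotypic()]).
#' @param ontology The phenotype `phen_ontology`.
#' @param mondo Optional MONDO `phen_ontology` for id unification.
#' @param unknown_default Frequency for annotations without one; see
#'   [resolve_frequency()].
#' @return A `phen_corpus` tibble: one row per disease-term pair with
#'   columns `disease_id`, `disease_name`, `term_id`, `frequency`.
#'   Attributes record corpus size and unmapped-id counts.
#' @export
build_corpus <- function(annotations, ontology, mondo = NULL,
                         unknown_default = 0.5) {
  ann <- annotations
  ann$term_id <- resolve_term_ids(ontology, ann$hpo_id)
  if (!is.null(mondo)) {
    m <- map_to_mondo(ann$database_id, mondo)
    ann$disease_id <- m$unified_id
    n_unmapped <- length(unique(m$disease_id[!m$mapped]))
  } else {
    ann$disease_id <- ann$database_id
    n_unmapped <- NA_integer_
  }
  freq <- resolve_frequency(ann$frequency, unknown_default = unknown_default)
  ann <- dplyr::bind_cols(
    dplyr::select(ann, "disease_id", "term_id",
                  dplyr::any_of("disease_name")),
    freq
  )
  if (!"disease_name" %in% names(ann)) ann$disease_name <- ann$disease_id

  out <- ann |>
    dplyr::group_by(.data$disease_id, .data$term_id) |>
    dplyr::arrange(.data$value, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      merged <- merge_duplicates(d[, c("value", "weight", "lo", "hi")])
      tibble::tibble(disease_name = d$disease_name[1],
                     frequency = merged$value)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$disease_id, .data$term_id) |>
    dplyr::select("disease_id", "disease_name", "term_id", "frequency")

  attr(out, "n_diseases") <- length(unique(out$disease_id))
  attr(out, "n_unmapped") <- n_unmapped
  class(out) <- c("phen_corpus", class(out))
  out
}

#' @method glance phen_corpus
#' @export
glance.phen_corpus <- function(x, ...) {
  tibble::tibble(
    n_diseases = length(unique(x$disease_id)),
    n_annotations = nrow(x),
    n_terms = length(unique(x$term_id)),
    mean_terms_per_disease = nrow(x) / length(unique(x$disease_id))
  )
}

#' Write / read a corpus as tab-separated text
#'
#' The on-disk form is a plain TSV (`disease_id`, `disease_name`,
#' `term_id`, `frequency`) so corpora can be inspected and versioned.
#'
#' @param corpus A `phen_corpus` tibble.
#' @param path Output path.
#' @return `path` invisibly; `read_corpus()` returns the corpus tibble.
#' @export
write_corpus <- function(corpus, path) {
  readr::write_tsv(as.data.frame(corpus), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  out <- readr::read_tsv(path, col_types = "cccd", progress = FALSE)
  attr(out, "n_diseases") <- length(unique(out$disease_id))
  class(out) <- c("phen_corpus", class(out))
  out
}
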