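# Query profile: the (term, frequency) set describing the condition under
# study. The packaged example is a Minamata-disease symptom profile whose
# headline values (the 0.37% intellectual-disability frequency, the
# spasticity and hypotonia terms, the 269 surveyed patients) are pinned and
# whose remaining frequencies are synthetic stand-ins.

#' Load a query profile from tab-separated text
#'
#' The format is a TSV with columns `symptom_label` (optional), `term_id`
#' (or `term`) and `frequency`, preceded by optional metadata comment lines
#' `# label: ...` and `# n_patients: ...`. Frequencies are probabilities in
#' \[0, 1\]; duplicate terms are merged by the duplicate-resolution rules of
#' [merge_duplicates()].
#'
#' @param file Path to a profile TSV, or a character vector of its lines.
#' @return A `phen_profile` tibble (`symptom_label`, `term_id`,
#'   `frequency`) with attributes `label` and `n_patients`.
#' @export
load_profile <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readr::read_lines(file)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  meta <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 2L) rlang::abort("profile file has no data rows")

  get_meta <- function(key) {
    hit <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    sub(sprintf("^#\\s*%s:\\s*", key), "", hit[1])
  }

  tbl <- readr::read_tsv(
    I(paste(body, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if ("term" %in% names(tbl) && !"term_id" %in% names(tbl)) {
    names(tbl)[names(tbl) == "term"] <- "term_id"
  }
  if (!all(c("term_id", "frequency") %in% names(tbl))) {
    rlang::abort("profile must have columns term_id (or term) and frequency")
  }
  if (!"symptom_label" %in% names(tbl)) tbl$symptom_label <- tbl$term_id
  freq <- suppressWarnings(as.numeric(tbl$frequency))
  bad <- is.na(freq) | freq < 0 | freq > 1
  if (any(bad)) {
    rlang::abort(sprintf(
      "frequency outside [0, 1] (or unparseable) at data row %d: %s",
      which(bad)[1], tbl$frequency[bad][1]
    ))
  }
  tbl$frequency <- freq

  out <- tbl |>
    dplyr::group_by(.data$term_id) |>
    dplyr::group_modify(function(d, key) {
      merged <- merge_duplicates(tibble::tibble(
        value = d$frequency, weight = NA_real_, lo = NA_real_, hi = NA_real_
      ))
      tibble::tibble(symptom_label = d$symptom_label[1],
                     frequency = merged$value)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("symptom_label", "term_id", "frequency")
  # preserve file row order after the grouped merge
  out <- out[order(match(out$term_id, tbl$term_id)), , drop = FALSE]

  attr(out, "label") <- get_meta("label")
  n_pat <- get_meta("n_patients")
  attr(out, "n_patients") <- if (is.na(n_pat)) NA_integer_ else as.integer(n_pat)
  class(out) <- c("phen_profile", class(out))
  out
}

#' @rdname load_profile
#' @param profile A `phen_profile` tibble.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  header <- character(0)
  if (!is.na(attr(profile, "label") %||% NA)) {
    header <- c(header, sprintf("# label: %s", attr(profile, "label")))
  }
  if (!is.na(attr(profile, "n_patients") %||% NA)) {
    header <- c(header, sprintf("# n_patients: %d", attr(profile, "n_patients")))
  }
  body <- readr::format_tsv(
    as.data.frame(profile[, c("symptom_label", "term_id", "frequency")])
  )
  readr::write_lines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' The packaged Minamata-disease query profile
#'
#' Loads the profile shipped with the package: symptoms of patients
#' diagnosed with Minamata disease in the Minamata area (n = 269), mapped
#' to phenotype-ontology terms. The intellectual-disability term carries
#' the corrected survey frequency of 0.37% (the larger conflicting value in
#' the historical source was discarded). All other frequencies in this file
#' are synthetic placeholders, generated once under a fixed seed so the
#' full pipeline is runnable without the original survey tables; supply
#' your own profile TSV for real analyses.
#'
#' @return A `phen_profile` tibble.
#' @export
minamata_profile <- function() {
  load_profile(system.file("extdata", "minamata_profile_synthetic.tsv",
                           package = "phenonet", mustWork = TRUE))
}

#' @method glance phen_profile
#' @export
glance.phen_profile <- function(x, ...) {
  tibble::tibble(
    label = attr(x, "label") %||% NA_character_,
    n_terms = nrow(x),
    n_patients = attr(x, "n_patients") %||% NA_integer_,
    mean_frequency = mean(x$frequency)
  )
}
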