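#' Disease annotation corpora
#'
#' A corpus maps each disease to the set of ontology terms that describe it.
#' In the intended use the set for an OMIM disease is the union of the MeSH
#' Main Headings indexing the publications its entry references; the type
#' itself is agnostic and works for any disease -> term-set map. The
#' `universe` records every disease considered, annotated or not, so that
#' coverage can be computed.
#'
#' @param annotations Named list: disease id -> character vector of term ids,
#'   or a data frame with columns `disease_id`, `term_id`.
#' @param universe Character vector of disease ids; defaults to the annotated
#'   diseases. Annotated diseases are always included.
#' @param provenance Optional named list: disease id -> publication ids.
#' @return An object of class `annotation_corpus`.
#' @export
annotation_corpus <- function(annotations, universe = NULL, provenance = NULL) {
  sets <- as_id_sets(annotations, "disease_id", "term_id")
  universe <- sort(unique(c(names(sets), as.character(universe %||% character()))))
  missing <- setdiff(universe, names(sets))
  if (length(missing)) sets[missing] <- rep(list(character()), length(missing))
  structure(
    list(annotations = sets[order(names(sets))], universe = universe,
         provenance = provenance),
    class = "annotation_corpus"
  )
}

#' @export
print.annotation_corpus <- function(x, ...) {
  n_ann <- sum(lengths(x$annotations) > 0L)
  cat(sprintf("<annotation_corpus> %d diseases in universe, %d annotated, %d distinct terms\n",
              length(x$universe), n_ann,
              length(unique(unlist(x$annotations, use.names = FALSE)))))
  invisible(x)
}

#' @method tidy annotation_corpus
#' @export
tidy.annotation_corpus <- function(x, ...) {
  lens <- lengths(x$annotations)
  tibble::tibble(
    disease_id = rep(names(x$annotations), pmax(lens, 1L)),
    term_id = unlist(lapply(x$annotations, function(v) {
      if (length(v)) v else NA_character_
    }), use.names = FALSE)
  ) |> dplyr::arrange(.data$disease_id, .data$term_id)
}

#' Annotation terms of one disease
#' @param c An `annotation_corpus`.
#' @param disease A disease id.
#' @return Character vector of term ids (possibly empty).
#' @export
disease_terms <- function(c, disease) {
  stopifnot(inherits(c, "annotation_corpus"))
  if (!disease %in% c$universe) abort(paste0("Unknown disease '", disease, "'."))
  c$annotations[[disease]] %||% character()
}

#' Build a corpus from disease -> publication and publication -> term maps
#'
#' The annotation set of a disease is the union of the term sets of its
#' referenced publications. Publications absent from `pub_terms` contribute
#' nothing (reported via a message, never an error), so a disease whose
#' references are all unknown stays in the universe with an empty set.
#'
#' @param disease_pubs Named list disease id -> publication ids, or a data
#'   frame with columns `disease_id`, `pub_id`.
#' @param pub_terms Named list publication id -> term ids, or a data frame
#'   with columns `pub_id`, `term_id`.
#' @return An `annotation_corpus` whose universe is the set of diseases in
#'   `disease_pubs` and whose provenance records each disease's publications.
#' @export
build_corpus <- function(disease_pubs, pub_terms) {
  dp <- as_id_sets(disease_pubs, "disease_id", "pub_id")
  pt <- as_id_sets(pub_terms, "pub_id", "term_id")
  known <- names(pt)
  n_missing <- length(setdiff(unique(unlist(dp, use.names = FALSE)), known))
  if (n_missing > 0L) {
    inform(sprintf("build_corpus: %d referenced publication(s) have no term data.",
                   n_missing))
  }
  sets <- lapply(dp, function(pubs) {
    sort(unique(unlist(pt[intersect(pubs, known)], use.names = FALSE)))
  })
  annotation_corpus(sets, universe = names(dp), provenance = dp)
}

#' Restrict a corpus to the terms of an ontology
#'
#' Intersects every annotation set with the ontology's term ids. Diseases are
#' never dropped (the universe is unchanged); the number of removed term
#' assignments is reported via a message.
#'
#' @param c An `annotation_corpus`.
#' @param o A `mesh_ontology`.
#' @return An `annotation_corpus`.
#' @export
restrict_to_ontology <- function(c, o) {
  stopifnot(inherits(c, "annotation_corpus"), inherits(o, "mesh_ontology"))
  keep <- ontology_terms(o)
  before <- sum(lengths(c$annotations))
  sets <- lapply(c$annotations, function(s) sort(intersect(s, keep)))
  dropped <- before - sum(lengths(sets))
  if (dropped > 0L) {
    inform(sprintf("restrict_to_ontology: dropped %d term assignment(s) outside the ontology.",
                   dropped))
  }
  annotation_corpus(sets, universe = c$universe, provenance = c$provenance)
}

#' Coverage of a corpus by an ontology
#'
#' The fraction of universe diseases having at least one annotation term
#' present in the ontology — i.e. the fraction of diseases for which
#' ontology-based similarities can be computed at all. Methods restricted to
#' a low-coverage branch can only score few diseases, which is why coverage
#' enters the composite evaluation score alongside AUC.
#'
#' @param c An `annotation_corpus` with a non-empty universe.
#' @param o A `mesh_ontology`.
#' @return A number in `[0, 1]`.
#' @export
corpus_coverage <- function(c, o) {
  stopifnot(inherits(c, "annotation_corpus"), inherits(o, "mesh_ontology"))
  if (length(c$universe) == 0L) abort("Corpus universe is empty.")
  keep <- ontology_terms(o)
  covered <- vapply(c$universe, function(d) {
    length(intersect(c$annotations[[d]] %||% character(), keep)) > 0L
  }, TRUE)
  mean(covered)
}

#' Read / write the corpus TSV dialect
#'
#' TSV with header `disease_id  term_id`; one row per (disease, term). A row
#' with an empty `term_id` places the disease in the universe with no
#' annotations. The writer emits rows sorted by `(disease_id, term_id)` for
#' bit-exact round trips.
#'
#' @param path File path.
#' @return `read_corpus_tsv()` returns an `annotation_corpus`;
#'   `write_corpus_tsv()` returns `path` invisibly.
#' @export
read_corpus_tsv <- function(path) {
  rows <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (!all(c("disease_id", "term_id") %in% names(rows))) {
    abort("Corpus TSV must have columns disease_id, term_id.")
  }
  bad <- which(is.na(rows$disease_id) | rows$disease_id == "")
  if (length(bad)) {
    abort(paste0("Malformed corpus TSV: empty disease_id at data line ",
                 bad[[1L]], "."))
  }
  annotation_corpus(rows, universe = unique(rows$disease_id))
}

#' @rdname read_corpus_tsv
#' @param c An `annotation_corpus`.
#' @export
write_corpus_tsv <- function(c, path) {
  stopifnot(inherits(c, "annotation_corpus"))
  out <- tidy(c)
  out$term_id[is.na(out$term_id)] <- ""
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read MEDLINE-format MH fields
#'
#' Minimal reader for MEDLINE text exports: `PMID-` lines start a record and
#' `MH  -` lines carry Main Headings. Qualifier strings after `/` are
#' stripped and the leading `*` major-topic marker is ignored, so all
#' headings are weighted equally.
#'
#' @param path Path to a MEDLINE text file.
#' @return A tibble with columns `pub_id`, `heading`.
#' @export
read_medline_mh <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  pmid <- NA_character_
  out <- vector("list", length(lines))
  k <- 0L
  for (ln in lines) {
    if (startsWith(ln, "PMID-")) {
      pmid <- trimws(sub("^PMID-", "", ln))
    } else if (startsWith(ln, "MH  -")) {
      if (is.na(pmid)) abort("MEDLINE MH line before any PMID record.")
      h <- trimws(sub("^MH  -", "", ln))
      h <- sub("/.*$", "", h)
      h <- sub("^\\*", "", h)
      k <- k + 1L
      out[[k]] <- tibble::tibble(pub_id = pmid, heading = h)
    }
  }
  if (k == 0L) return(tibble::tibble(pub_id = character(), heading = character()))
  dplyr::distinct(dplyr::bind_rows(out[seq_len(k)]))
}

#' Resolve heading names to descriptor ids by exact preferred-name match
#'
#' @param headings Tibble with columns `pub_id`, `heading` (as returned by
#'   [read_medline_mh()]).
#' @param o A `mesh_ontology` whose term names are the match targets.
#' @return A tibble `pub_id`, `term_id`; headings with no exact match are
#'   dropped and their count reported via a message.
#' @export
resolve_headings <- function(headings, o) {
  stopifnot(inherits(o, "mesh_ontology"))
  res <- dplyr::inner_join(headings, o$terms, by = c(heading = "name"))
  n_miss <- length(setdiff(unique(headings$heading), o$terms$name))
  if (n_miss > 0L) {
    inform(sprintf("resolve_headings: %d heading(s) had no exact preferred-name match.",
                   n_miss))
  }
  dplyr::distinct(res[, c("pub_id", "term_id")])
}
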