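#' Information content of ontology terms
#'
#' The information content (IC) of a term is the negative natural logarithm
#' of its annotation probability: the number of diseases annotated by the
#' term (directly or through any descendant, by the True Path Rule) divided
#' by the total number of annotated diseases. Rare, specific terms get high
#' IC; the root, which annotates everything, gets IC 0.
#'
#' Counts propagate through *all* parents of multi-parent terms, and each
#' disease contributes at most once to each term's count. Terms reached by
#' no disease are absent from the table and unusable for scoring.
#'
#' @param o A `mesh_ontology`.
#' @param c An `annotation_corpus` (terms outside `o` are ignored).
#' @return An object of class `ic_table`: a list with `ic` (named numeric,
#'   natural-log units), `counts` (named integer), `n_diseases` and a cache
#'   environment for derived term-similarity matrices.
#' @export
compute_ic <- function(o, c) {
  stopifnot(inherits(o, "mesh_ontology"), inherits(c, "annotation_corpus"))
  keep <- ontology_terms(o)
  closures <- lapply(c$annotations, function(terms) {
    terms <- intersect(terms, keep)
    if (length(terms) == 0L) return(NULL)
    unique(unlist(lapply(terms, term_ancestors, o = o), use.names = FALSE))
  })
  closures <- closures[!vapply(closures, is.null, TRUE)]
  n <- length(closures)
  if (n == 0L) abort("No disease has any annotation term inside the ontology.")
  tab <- table(unlist(closures, use.names = FALSE))
  counts <- setNames(as.integer(tab), names(tab))
  counts <- counts[order(names(counts))]
  structure(
    list(ic = -log(counts / n), counts = counts, n_diseases = n,
         cache = new.env(parent = emptyenv())),
    class = "ic_table"
  )
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("<ic_table> %d terms with finite IC over %d annotated diseases (max IC %.4f)\n",
              length(x$ic), x$n_diseases, max(x$ic)))
  invisible(x)
}

#' @method tidy ic_table
#' @export
tidy.ic_table <- function(x, ...) {
  tibble::tibble(term_id = names(x$ic),
                 count = as.integer(x$counts[names(x$ic)]),
                 ic = unname(x$ic))
}

usable_ic <- function(ict, t) {
  v <- ict$ic[t]
  if (anyNA(v)) {
    abort(paste0("Term(s) without finite information content: ",
                 paste(t[is.na(v)], collapse = ", ")))
  }
  unname(v)
}

#' Term-level semantic similarity
#'
#' `resnik_term()` is the IC of the most informative common ancestor of the
#' two terms (ancestor sets are reflexive, so `resnik_term(t, t)` equals
#' `IC(t)`; the synthetic root guarantees at least one common ancestor).
#' `lin_term()` normalises it, `2*resnik / (IC(t1) + IC(t2))`, with the
#' degenerate `0/0` case (two fully uninformative terms) defined as 1.
#' `jiang_term()` turns the Jiang–Conrath distance
#' `d = IC(t1) + IC(t2) - 2*resnik` into a similarity `1 - d/M`, where `M`
#' is the maximum of `d` over all term pairs with finite IC in this
#' (ontology, IC table); `M` is computed once and cached. When `M = 0` the
#' similarity is identically 1.
#'
#' @param t1,t2 Term ids with finite IC.
#' @param o A `mesh_ontology`.
#' @param ict An `ic_table` computed on `o`.
#' @return A similarity: Resnik in `[0, -ln(1/n_diseases)]`, Lin and Jiang
#'   in `[0, 1]`.
#' @export
resnik_term <- function(t1, t2, o, ict) {
  usable_ic(ict, c(t1, t2))
  common <- intersect(term_ancestors(o, t1), term_ancestors(o, t2))
  ic <- ict$ic[common]
  max(ic[!is.na(ic)], 0)
}

#' @rdname resnik_term
#' @export
lin_term <- function(t1, t2, o, ict) {
  denom <- sum(usable_ic(ict, c(t1, t2)))
  if (denom == 0) return(1)
  2 * resnik_term(t1, t2, o, ict) / denom
}

#' @rdname resnik_term
#' @export
jiang_term <- function(t1, t2, o, ict) {
  ic12 <- usable_ic(ict, c(t1, t2))
  M <- jiang_max_distance(o, ict)
  if (M == 0) return(1)
  d <- sum(ic12) - 2 * resnik_term(t1, t2, o, ict)
  1 - d / M
}

#' Maximum Jiang-Conrath distance over a (ontology, IC table) pair
#'
#' @inheritParams resnik_term
#' @return The normalising constant `M` used by [jiang_term()].
#' @export
jiang_max_distance <- function(o, ict) {
  cached <- ict$cache$jiang_M
  if (!is.null(cached)) return(cached)
  S <- term_sim_matrix(o, ict, "resnik")
  ic <- ict$ic[rownames(S)]
  D <- outer(ic, ic, "+") - 2 * S
  M <- max(D, 0)
  assign("jiang_M", M, envir = ict$cache)
  M
}

# Dense term-by-term similarity matrix over all terms with finite IC
# (synthetic root included). Cached per ic_table; the Resnik matrix is the
# primitive, Lin and Jiang matrices are derived from it.
term_sim_matrix <- function(o, ict, measure) {
  key <- paste0("mat_", measure)
  cached <- ict$cache[[key]]
  if (!is.null(cached)) return(cached)
  if (measure %in% c("lin", "jiang")) {
    R <- term_sim_matrix(o, ict, "resnik")
    ic <- ict$ic[rownames(R)]
    if (measure == "lin") {
      denom <- outer(ic, ic, "+")
      S <- 2 * R / denom
      S[denom == 0] <- 1
    } else {
      M <- jiang_max_distance(o, ict)
      if (M == 0) {
        S <- matrix(1, nrow(R), ncol(R), dimnames = dimnames(R))
      } else {
        S <- 1 - (outer(ic, ic, "+") - 2 * R) / M
      }
    }
    assign(key, S, envir = ict$cache)
    return(S)
  }
  terms <- names(ict$ic)
  nt <- length(terms)
  ic <- unname(ict$ic)
  # logical incidence: A[i, k] = terms[k] is an ancestor of terms[i]
  A <- matrix(FALSE, nt, nt, dimnames = list(terms, terms))
  for (i in seq_len(nt)) {
    anc <- term_ancestors(o, terms[[i]])
    A[i, match(intersect(anc, terms), terms)] <- TRUE
  }
  S <- matrix(0, nt, nt, dimnames = list(terms, terms))
  for (i in seq_len(nt)) {
    Ai <- A[i, ]
    for (j in i:nt) {
      common <- Ai & A[j, ]
      S[i, j] <- S[j, i] <- if (any(common)) max(ic[common]) else 0
    }
  }
  assign(key, S, envir = ict$cache)
  S
}

#' Disease-level semantic similarity (max over annotation term pairs)
#'
#' The similarity of two diseases is the maximum term-level similarity over
#' all pairs of terms annotating them, using only terms with finite IC. If
#' either disease has no usable term the similarity is *undefined* and
#' `NA_real_` is returned — that is a value, not an error, and such pairs
#' are what the coverage statistic accounts for.
#'
#' @param a,b Disease ids in the corpus universe.
#' @param c An `annotation_corpus`.
#' @param o A `mesh_ontology`.
#' @param ict An `ic_table` computed on `o`.
#' @param term_measure One of `"resnik"`, `"lin"`, `"jiang"`.
#' @return A similarity score, or `NA_real_` when undefined.
#' @export
disease_similarity <- function(a, b, c, o, ict,
                               term_measure = c("resnik", "lin", "jiang")) {
  term_measure <- match.arg(term_measure)
  ta <- intersect(disease_terms(c, a), names(ict$ic))
  tb <- intersect(disease_terms(c, b), names(ict$ic))
  if (length(ta) == 0L || length(tb) == 0L) return(NA_real_)
  f <- switch(term_measure, resnik = resnik_term, lin = lin_term,
              jiang = jiang_term)
  best <- -Inf
  for (t1 in ta) for (t2 in tb) {
    best <- max(best, f(t1, t2, o, ict))
  }
  best
}

# Ancestor-expanded annotation set of one disease (True Path Rule).
expanded_terms <- function(d, c, o) {
  terms <- intersect(disease_terms(c, d), ontology_terms(o))
  if (length(terms) == 0L) return(character())
  unique(unlist(lapply(terms, term_ancestors, o = o), use.names = FALSE))
}

#' Graph-based set similarities: simUI and simGIC
#'
#' Both expand each disease's annotation set with all ancestors up to the
#' root (True Path Rule) and compare the expansions. `simui()` is their
#' Jaccard coefficient; `simgic()` is the IC-weighted Jaccard coefficient,
#' where each term contributes its information content (terms without finite
#' IC, and the root, weigh 0). If an IC-weighted denominator is 0 the two
#' expansions are indistinguishable and the similarity is 1.
#'
#' @inheritParams disease_similarity
#' @return A similarity in `[0, 1]`, or `NA_real_` when either expansion is
#'   empty.
#' @export
simui <- function(a, b, c, o) {
  ua <- expanded_terms(a, c, o)
  ub <- expanded_terms(b, c, o)
  if (length(ua) == 0L || length(ub) == 0L) return(NA_real_)
  length(intersect(ua, ub)) / length(union(ua, ub))
}

#' @rdname simui
#' @export
simgic <- function(a, b, c, o, ict) {
  ua <- expanded_terms(a, c, o)
  ub <- expanded_terms(b, c, o)
  if (length(ua) == 0L || length(ub) == 0L) return(NA_real_)
  w <- function(t) {
    v <- ict$ic[t]
    sum(v[!is.na(v)])
  }
  denom <- w(union(ua, ub))
  if (denom == 0) return(1)
  w(intersect(ua, ub)) / denom
}

#' Set-overlap baseline measures
#'
#' Measures that ignore the ontology structure entirely and compare the raw
#' (unexpanded) annotation sets: Jaccard, Sorensen-Dice, overlap coefficient
#' and the plain intersection size. They weigh a broad heading exactly like a
#' specific one, which is what the ontology-based measures are designed to
#' avoid.
#'
#' @inheritParams disease_similarity
#' @param kind One of `"jaccard"`, `"dice"`, `"overlap"`, `"num_common"`.
#' @return The score, or `NA_real_` when either raw set is empty.
#' @export
overlap_measure <- function(a, b, c,
                            kind = c("jaccard", "dice", "overlap", "num_common")) {
  kind <- match.arg(kind)
  A <- disease_terms(c, a)
  B <- disease_terms(c, b)
  if (length(A) == 0L || length(B) == 0L) return(NA_real_)
  ni <- length(intersect(A, B))
  switch(kind,
         jaccard = ni / length(union(A, B)),
         dice = 2 * ni / (length(A) + length(B)),
         overlap = ni / min(length(A), length(B)),
         num_common = ni)
}

SIM_MEASURES <- c("resnik", "lin", "jiang", "simui", "simgic",
                  "jaccard", "dice", "overlap", "num_common")

#' Score every unordered disease pair
#'
#' Computes the chosen similarity measure for all unordered pairs of
#' distinct diseases (by default the whole corpus universe). Pairs for which
#' the measure is undefined are recorded separately rather than imputed.
#'
#' @param c An `annotation_corpus`.
#' @param o A `mesh_ontology` (unused by the raw overlap measures).
#' @param ict An `ic_table` (needed by resnik/lin/jiang/simgic).
#' @param measure One of `"resnik"`, `"lin"`, `"jiang"`, `"simui"`,
#'   `"simgic"`, `"jaccard"`, `"dice"`, `"overlap"`, `"num_common"`.
#' @param disease_subset Optional character vector restricting the diseases.
#' @param ontology_tag Label recorded in the result (defaults to the
#'   ontology's branch letters).
#' @return A `similarity_result`: list with `scores` (tibble `disease_a`,
#'   `disease_b`, `score`, pairs lexicographically ordered),
#'   `undefined_pairs` (tibble of unscorable pairs), `measure` and
#'   `ontology_tag`.
#' @export
all_pairs <- function(c, o = NULL, ict = NULL, measure = "resnik",
                      disease_subset = NULL, ontology_tag = NULL) {
  measure <- match.arg(measure, SIM_MEASURES)
  stopifnot(inherits(c, "annotation_corpus"))
  needs_ont <- measure %in% c("resnik", "lin", "jiang", "simui", "simgic")
  needs_ic <- measure %in% c("resnik", "lin", "jiang", "simgic")
  if (needs_ont) stopifnot(inherits(o, "mesh_ontology"))
  if (needs_ic) stopifnot(inherits(ict, "ic_table"))
  diseases <- sort(unique(disease_subset %||% c$universe))
  stopifnot(all(diseases %in% c$universe))
  pairs <- all_unordered_pairs(diseases)

  score_fun <- NULL
  if (measure %in% c("resnik", "lin", "jiang")) {
    S <- term_sim_matrix(o, ict, measure)
    idx <- lapply(diseases, function(d) {
      match(intersect(disease_terms(c, d), rownames(S)), rownames(S))
    })
    names(idx) <- diseases
    score_fun <- function(a, b) {
      ia <- idx[[a]]; ib <- idx[[b]]
      if (length(ia) == 0L || length(ib) == 0L) return(NA_real_)
      max(S[ia, ib, drop = FALSE])
    }
  } else if (measure %in% c("simui", "simgic")) {
    exps <- lapply(diseases, expanded_terms, c = c, o = o)
    names(exps) <- diseases
    if (measure == "simui") {
      score_fun <- function(a, b) {
        ua <- exps[[a]]; ub <- exps[[b]]
        if (length(ua) == 0L || length(ub) == 0L) return(NA_real_)
        length(intersect(ua, ub)) / length(union(ua, ub))
      }
    } else {
      icv <- ict$ic
      score_fun <- function(a, b) {
        ua <- exps[[a]]; ub <- exps[[b]]
        if (length(ua) == 0L || length(ub) == 0L) return(NA_real_)
        wu <- icv[union(ua, ub)]
        denom <- sum(wu[!is.na(wu)])
        if (denom == 0) return(1)
        wi <- icv[intersect(ua, ub)]
        sum(wi[!is.na(wi)]) / denom
      }
    }
  } else {
    score_fun <- function(a, b) overlap_measure(a, b, c, kind = measure)
  }

  scores <- vapply(seq_len(nrow(pairs)), function(k) {
    score_fun(pairs$disease_a[[k]], pairs$disease_b[[k]])
  }, numeric(1))
  defined <- !is.na(scores)
  tag <- ontology_tag %||%
    (if (needs_ont) paste(o$categories, collapse = "") else "raw")
  new_similarity_result(
    scores = dplyr::mutate(pairs[defined, ], score = scores[defined]),
    undefined_pairs = pairs[!defined, ],
    measure = measure, ontology_tag = tag
  )
}

new_similarity_result <- function(scores, undefined_pairs, measure,
                                  ontology_tag) {
  structure(
    list(scores = tibble::as_tibble(scores),
         undefined_pairs = tibble::as_tibble(undefined_pairs),
         measure = measure, ontology_tag = ontology_tag),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> measure=%s ontology=%s: %d scored, %d undefined pair(s)\n",
              x$measure, x$ontology_tag, nrow(x$scores),
              nrow(x$undefined_pairs)))
  if (nrow(x$scores)) print(utils::head(x$scores, 5))
  invisible(x)
}

#' @method tidy similarity_result
#' @export
tidy.similarity_result <- function(x, ...) x$scores

#' @method glance similarity_result
#' @export
glance.similarity_result <- function(x, ...) {
  tibble::tibble(measure = x$measure, ontology_tag = x$ontology_tag,
                 n_scored = nrow(x$scores),
                 n_undefined = nrow(x$undefined_pairs),
                 min_score = if (nrow(x$scores)) min(x$scores$score) else NA_real_,
                 max_score = if (nrow(x$scores)) max(x$scores$score) else NA_real_)
}

#' Combine per-branch similarity results by taking the maximum
#'
#' Alternative to scoring on one merged ontology: score each branch
#' separately and keep, for every disease pair, the maximum score across
#' branches. A pair is undefined only if it is undefined in every branch.
#'
#' @param results A list of `similarity_result` objects for the same measure
#'   over the same diseases.
#' @return A `similarity_result` tagged with the combined branch labels.
#' @export
combine_branch_scores <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "similarity_result")))
  measures <- unique(vapply(results, function(r) r$measure, ""))
  if (length(measures) != 1L) {
    abort("All results must use the same measure.")
  }
  scored <- dplyr::bind_rows(lapply(results, function(r) r$scores))
  best <- scored |>
    dplyr::group_by(.data$disease_a, .data$disease_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$disease_a, .data$disease_b)
  all_pairs_seen <- dplyr::distinct(dplyr::bind_rows(
    lapply(results, function(r) dplyr::bind_rows(r$scores[, 1:2],
                                                 r$undefined_pairs))
  ))
  undef <- dplyr::anti_join(all_pairs_seen, best,
                            by = c("disease_a", "disease_b")) |>
    dplyr::arrange(.data$disease_a, .data$disease_b)
  new_similarity_result(
    best, undef, measures,
    paste0("max(", paste(vapply(results, function(r) r$ontology_tag, ""),
                         collapse = ","), ")")
  )
}

#' Read / write the similarity-matrix TSV dialect
#'
#' TSV `disease_a  disease_b  score`, unordered pairs emitted once and
#' sorted lexicographically; undefined pairs are omitted from the TSV and a
#' JSON sidecar records the measure, ontology tag, number of annotated
#' diseases and (for Jiang) the normalising constant `M`.
#'
#' @param result A `similarity_result`.
#' @param path TSV path; the sidecar is written to `paste0(path, ".meta.json")`.
#' @param n_diseases,jiang_M Optional metadata written to the sidecar.
#' @return `write_similarity_tsv()` returns `path` invisibly;
#'   `read_similarity_tsv()` returns a `similarity_result` (undefined pairs
#'   are not recoverable from the file and come back empty).
#' @export
write_similarity_tsv <- function(result, path, n_diseases = NA,
                                 jiang_M = NA) {
  stopifnot(inherits(result, "similarity_result"))
  out <- dplyr::arrange(result$scores, .data$disease_a, .data$disease_b)
  readr::write_tsv(out, path, progress = FALSE)
  meta <- list(measure = result$measure, ontology_tag = result$ontology_tag,
               n_scored = nrow(out), n_undefined = nrow(result$undefined_pairs),
               n_diseases = n_diseases, jiang_M = jiang_M)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  rows <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  new_similarity_result(
    rows,
    tibble::tibble(disease_a = character(), disease_b = character()),
    measure = meta$measure %||% "unknown",
    ontology_tag = meta$ontology_tag %||% "unknown"
  )
}
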