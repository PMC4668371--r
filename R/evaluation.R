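#' Molecular-relatedness gold standards
#'
#' The evaluation treats disease similarity as a score for a binary
#' classification problem: are two diseases related at the molecular level?
#' Three relationships define the positive class — disease proteins that
#' interact, disease proteins sharing a Pfam-A signature, and disease
#' proteins with highly similar sequences. Diseases enter a dataset's
#' `eligible` set when they have at least one known protein; negatives are
#' all eligible pairs not labelled positive.
#'
#' @name relationship_dataset
NULL

new_relationship_dataset <- function(positives, eligible, name) {
  positives <- dplyr::distinct(tibble::as_tibble(positives))
  positives <- dplyr::arrange(positives, .data$disease_a, .data$disease_b)
  structure(list(positives = positives, eligible = sort(unique(eligible)),
                 name = name),
            class = "relationship_dataset")
}

#' @export
print.relationship_dataset <- function(x, ...) {
  cat(sprintf("<relationship_dataset '%s'> %d positive pair(s) over %d eligible disease(s)\n",
              x$name, nrow(x$positives), length(x$eligible)))
  invisible(x)
}

#' @method tidy relationship_dataset
#' @export
tidy.relationship_dataset <- function(x, ...) x$positives

# distinct canonical disease pairs from two parallel vectors
canonical_pair_tbl <- function(a, b) {
  keep <- a != b
  p <- canonical_pairs(a[keep], b[keep])
  dplyr::distinct(tibble::tibble(disease_a = p$a, disease_b = p$b))
}

#' Build the protein–protein-interaction gold standard
#'
#' Two diseases are related if any of their disease proteins interact (in
#' real use, according to a curated interaction database such as HPRD). A
#' protein's interaction with itself, if listed, also relates two diseases
#' that both carry that protein.
#'
#' @param disease_proteins Tibble `disease_id`, `protein_id` (or a named
#'   list disease -> proteins).
#' @param interactions Tibble `protein_a`, `protein_b` of unordered
#'   interacting pairs.
#' @return A `relationship_dataset` named `"ppi"`.
#' @export
build_ppi_dataset <- function(disease_proteins, interactions) {
  dp <- as_id_sets(disease_proteins, "disease_id", "protein_id")
  dp <- dp[lengths(dp) > 0L]
  prot2dis <- as_id_sets(
    tibble::tibble(protein_id = unlist(dp, use.names = FALSE),
                   disease_id = rep(names(dp), lengths(dp))),
    "protein_id", "disease_id"
  )
  ia <- as.character(interactions$protein_a)
  ib <- as.character(interactions$protein_b)
  pos_a <- character()
  pos_b <- character()
  for (k in seq_along(ia)) {
    d1 <- prot2dis[[ia[[k]]]] %||% character()
    d2 <- prot2dis[[ib[[k]]]] %||% character()
    if (length(d1) && length(d2)) {
      grid <- expand.grid(a = d1, b = d2, stringsAsFactors = FALSE)
      pos_a <- c(pos_a, grid$a)
      pos_b <- c(pos_b, grid$b)
    }
  }
  new_relationship_dataset(canonical_pair_tbl(pos_a, pos_b), names(dp), "ppi")
}

#' Build the shared Pfam-A-signature gold standard
#'
#' Two diseases are related if any of their proteins share at least one
#' Pfam-A signature (family, domain, motif or repeat). Two exclusions apply:
#' pairs where some shared signature's name matches a MeSH term name
#' (case-insensitive exact match) are removed, because such signatures can
#' leak annotation information; and pairs whose protein sets are identical
#' are removed, because they are trivially related.
#'
#' @inheritParams build_ppi_dataset
#' @param protein_signatures Tibble `protein_id`, `signature` (or named list).
#' @param mesh_names Character vector of term preferred names.
#' @return A `relationship_dataset` named `"pfam"`.
#' @export
build_pfam_dataset <- function(disease_proteins, protein_signatures,
                               mesh_names = character()) {
  dp <- as_id_sets(disease_proteins, "disease_id", "protein_id")
  dp <- dp[lengths(dp) > 0L]
  ps <- as_id_sets(protein_signatures, "protein_id", "signature")
  sig_sets <- lapply(dp, function(prots) {
    sort(unique(unlist(ps[intersect(prots, names(ps))], use.names = FALSE)))
  })
  banned <- tolower(as.character(mesh_names))
  ds <- names(dp)
  pairs <- all_unordered_pairs(ds)
  keep <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs$disease_a[[k]]
    b <- pairs$disease_b[[k]]
    shared <- intersect(sig_sets[[a]], sig_sets[[b]])
    if (length(shared) == 0L) return(FALSE)
    if (any(tolower(shared) %in% banned)) return(FALSE)
    !identical(dp[[a]], dp[[b]])
  }, TRUE)
  new_relationship_dataset(pairs[keep, ], ds, "pfam")
}

#' Build the sequence-similarity gold standard
#'
#' Two diseases are related if any cross-disease protein pair has a
#' (precomputed) Smith–Waterman alignment e-value at or below the threshold;
#' the threshold is inclusive. Pairs whose protein sets are identical are
#' excluded.
#'
#' @inheritParams build_ppi_dataset
#' @param evalues Tibble `protein_a`, `protein_b`, `evalue` of precomputed
#'   alignment e-values (unordered protein pairs).
#' @param threshold Inclusive e-value cutoff (default `1e-6`).
#' @return A `relationship_dataset` named `"seqsim"`.
#' @export
build_seqsim_dataset <- function(disease_proteins, evalues,
                                 threshold = 1e-6) {
  hits <- evalues[as.numeric(evalues$evalue) <= threshold, ]
  ds <- new_relationship_dataset(
    tibble::tibble(disease_a = character(), disease_b = character()),
    character(), "seqsim"
  )
  dp <- as_id_sets(disease_proteins, "disease_id", "protein_id")
  dp <- dp[lengths(dp) > 0L]
  similar <- new.env(parent = emptyenv())
  mark <- function(p, q) assign(paste(p, q, sep = "\r"), TRUE, envir = similar)
  for (k in seq_len(nrow(hits))) {
    p <- as.character(hits$protein_a[[k]])
    q <- as.character(hits$protein_b[[k]])
    mark(p, q); mark(q, p)
  }
  pairs <- all_unordered_pairs(names(dp))
  keep <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- dp[[pairs$disease_a[[k]]]]
    b <- dp[[pairs$disease_b[[k]]]]
    if (identical(a, b)) return(FALSE)
    for (p in a) for (q in b) {
      if (!is.null(similar[[paste(p, q, sep = "\r")]])) return(TRUE)
    }
    FALSE
  }, TRUE)
  new_relationship_dataset(pairs[keep, ], names(dp), "seqsim")
}

#' ROC-AUC of a similarity result against a gold standard
#'
#' Scores are evaluated as a classifier of molecular relatedness over all
#' eligible disease pairs: positives are the dataset's related pairs,
#' negatives every other eligible pair. Pairs with an undefined similarity
#' are dropped from both classes (coverage accounts for them separately).
#' The AUC is the Mann–Whitney rank statistic with average ranks for ties,
#' which equals the area under the empirical ROC curve with trapezoidal
#' interpolation.
#'
#' @param result A `similarity_result`.
#' @param gold A `relationship_dataset`.
#' @return A one-row tibble `dataset`, `auc`, `n_positive`, `n_negative`.
#' @export
roc_auc <- function(result, gold) {
  stopifnot(inherits(result, "similarity_result"),
            inherits(gold, "relationship_dataset"))
  pairs <- all_unordered_pairs(gold$eligible)
  pos_key <- pair_key(gold$positives$disease_a, gold$positives$disease_b)
  scored <- dplyr::inner_join(
    pairs, result$scores, by = c("disease_a", "disease_b")
  )
  labels <- pair_key(scored$disease_a, scored$disease_b) %in% pos_key
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L) abort(paste0("No scored positive pairs for dataset '",
                                gold$name, "'."))
  if (n_neg == 0L) abort(paste0("No scored negative pairs for dataset '",
                                gold$name, "'."))
  r <- rank(scored$score, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  tibble::tibble(dataset = gold$name, auc = auc,
                 n_positive = n_pos, n_negative = n_neg)
}

#' Evaluate a similarity measure: per-dataset AUC, coverage, composite
#'
#' The overall performance of a measure is summarised as the sum of its
#' ROC-AUCs over the gold-standard datasets plus its coverage of the disease
#' universe — the composite score visualised as total bar length in the
#' benchmark figures. Coverage penalises methods that can only score few
#' diseases, AUC rewards ranking related pairs above unrelated ones.
#'
#' @param result A `similarity_result`.
#' @param datasets A list of `relationship_dataset` objects (may be empty,
#'   in which case the composite is just the coverage).
#' @param c An `annotation_corpus` (for coverage).
#' @param o A `mesh_ontology` (for coverage).
#' @return An object of class `eval_report`.
#' @export
evaluate_measure <- function(result, datasets, c, o) {
  aucs <- if (length(datasets)) {
    purrr::map_dfr(datasets, roc_auc, result = result)
  } else {
    tibble::tibble(dataset = character(), auc = numeric(),
                   n_positive = integer(), n_negative = integer())
  }
  cov <- corpus_coverage(c, o)
  structure(
    list(aucs = aucs, coverage = cov,
         composite = cov + sum(aucs$auc),
         measure = result$measure, ontology_tag = result$ontology_tag),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> measure=%s coverage=%.3f composite=%.3f\n",
              x$measure, x$coverage, x$composite))
  if (nrow(x$aucs)) print(x$aucs)
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  cov_row <- tibble::tibble(measure = x$measure, component = "coverage",
                            value = x$coverage)
  if (nrow(x$aucs) == 0L) return(cov_row)
  dplyr::bind_rows(
    x$aucs |>
      dplyr::mutate(measure = x$measure, component = paste0("auc_", .data$dataset),
                    value = .data$auc) |>
      dplyr::select("measure", "component", "value"),
    cov_row
  )
}

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  wide <- tibble::tibble(measure = x$measure, coverage = x$coverage)
  for (k in seq_len(nrow(x$aucs))) {
    wide[[paste0("auc_", x$aucs$dataset[[k]])]] <- x$aucs$auc[[k]]
  }
  wide$composite <- x$composite
  wide
}

#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure, y = .data$value,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "coverage + AUCs (composite)",
                  title = sprintf("Composite performance: %.3f",
                                  object$composite)) +
    ggplot2::theme_minimal()
}

#' Benchmark several measures on one corpus and gold standards
#'
#' Runs [all_pairs()] and [evaluate_measure()] for each measure and returns
#' one row per measure, ordered by decreasing composite — the data behind
#' the benchmark bar charts.
#'
#' @inheritParams all_pairs
#' @param datasets A list of `relationship_dataset` objects.
#' @param measures Character vector of measure names (default all nine).
#' @return A tibble with columns `measure`, `coverage`, one `auc_*` column
#'   per dataset and `composite`.
#' @export
compare_measures <- function(c, o, ict, datasets, measures = SIM_MEASURES) {
  purrr::map_dfr(measures, function(m) {
    res <- all_pairs(c, o, ict, measure = m)
    glance(evaluate_measure(res, datasets, c, o))
  }) |>
    dplyr::arrange(dplyr::desc(.data$composite))
}

#' Compare score distributions of shared-gene pairs vs all pairs
#'
#' Disease pairs sharing at least one disease gene should concentrate in the
#' upper tail of the overall score distribution if the similarity reflects
#' molecular relatedness. This returns each shared-gene pair's percentile
#' within the all-pairs score distribution, the fraction of shared-gene
#' pairs at or above the 99th percentile, and a Welch two-sample t-test
#' between shared-gene and remaining pair scores.
#'
#' @param result A `similarity_result` with scored pairs.
#' @param disease_genes Tibble `disease_id`, `gene_id` (or named list).
#' @return An object of class `shared_gene_summary` with elements
#'   `all_scores`, `shared` (tibble with `score` and `percentile`),
#'   `fraction_at_99th`, `t_statistic`, `p_value`.
#' @export
shared_gene_analysis <- function(result, disease_genes) {
  stopifnot(inherits(result, "similarity_result"))
  if (nrow(result$scores) == 0L) abort("No scored pairs in result.")
  dg <- as_id_sets(disease_genes, "disease_id", "gene_id")
  sc <- result$scores
  is_shared <- vapply(seq_len(nrow(sc)), function(k) {
    ga <- dg[[sc$disease_a[[k]]]] %||% character()
    gb <- dg[[sc$disease_b[[k]]]] %||% character()
    length(intersect(ga, gb)) > 0L
  }, TRUE)
  if (!any(is_shared)) abort("No scored disease pair shares a gene.")
  all_scores <- sc$score
  shared_scores <- sc$score[is_shared]
  percentile <- vapply(shared_scores,
                       function(s) 100 * mean(all_scores <= s), 0)
  rest <- sc$score[!is_shared]
  tt <- if (length(shared_scores) >= 2L && length(rest) >= 2L) {
    stats::t.test(shared_scores, rest)
  } else NULL
  structure(
    list(all_scores = all_scores,
         shared = dplyr::mutate(sc[is_shared, ], percentile = percentile),
         fraction_at_99th = mean(percentile >= 99),
         t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
         p_value = if (is.null(tt)) NA_real_ else tt$p.value),
    class = "shared_gene_summary"
  )
}

#' @export
print.shared_gene_summary <- function(x, ...) {
  cat(sprintf("<shared_gene_summary> %d shared-gene pair(s) of %d scored; %.1f%% at/above the 99th percentile; Welch t=%.2f, p=%.3g\n",
              nrow(x$shared), length(x$all_scores),
              100 * x$fraction_at_99th, x$t_statistic, x$p_value))
  invisible(x)
}

#' @method glance shared_gene_summary
#' @export
glance.shared_gene_summary <- function(x, ...) {
  tibble::tibble(n_shared = nrow(x$shared), n_all = length(x$all_scores),
                 fraction_at_99th = x$fraction_at_99th,
                 t_statistic = x$t_statistic, p_value = x$p_value)
}

#' @method autoplot shared_gene_summary
#' @export
autoplot.shared_gene_summary <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(score = object$all_scores, group = "all pairs"),
    tibble::tibble(score = object$shared$score, group = "shared-gene pairs")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$group)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(.data$density)),
                            position = "identity", alpha = 0.55, bins = 30) +
    ggplot2::labs(x = "similarity score", y = "density",
                  title = "Score distributions: all pairs vs shared-gene pairs") +
    ggplot2::theme_minimal()
}

#' Table of the most similar disease pairs
#'
#' Returns the disease pairs whose score reaches the upper
#' `threshold_fraction` quantile of all scored pairs (ties at the boundary
#' are kept), with the proteins associated to each disease — the layout of a
#' downloadable top-similarity resource.
#'
#' @param result A `similarity_result`.
#' @param threshold_fraction Fraction of top pairs to keep, in `(0, 1]`
#'   (default 0.05).
#' @param disease_proteins Tibble `disease_id`, `protein_id` (or named
#'   list); proteins are comma-joined per disease.
#' @return A tibble `disease_a`, `disease_b`, `score`, `proteins_a`,
#'   `proteins_b`, sorted by descending score.
#' @export
top_percent_table <- function(result, threshold_fraction = 0.05,
                              disease_proteins = NULL) {
  stopifnot(inherits(result, "similarity_result"),
            threshold_fraction > 0, threshold_fraction <= 1)
  sc <- result$scores
  if (nrow(sc) == 0L) {
    return(tibble::tibble(disease_a = character(), disease_b = character(),
                          score = numeric(), proteins_a = character(),
                          proteins_b = character()))
  }
  cut <- stats::quantile(sc$score, probs = 1 - threshold_fraction,
                         names = FALSE, type = 7)
  out <- sc[sc$score >= cut, ]
  dp <- if (is.null(disease_proteins)) list() else
    as_id_sets(disease_proteins, "disease_id", "protein_id")
  fmt <- function(d) {
    vapply(d, function(x) paste(dp[[x]] %||% character(), collapse = ","), "")
  }
  out |>
    dplyr::mutate(proteins_a = fmt(.data$disease_a),
                  proteins_b = fmt(.data$disease_b)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$disease_a, .data$disease_b)
}
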