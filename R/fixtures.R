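#' Specification of a synthetic fixture
#'
#' The fixture generator emulates the statistical structure the pipeline is
#' built for: several category branches over a shared descriptor pool, with
#' a controlled fraction of descriptors placed in more than one branch
#' (which is what links branches on merging); multi-parent nodes; and a
#' disease corpus with planted clusters whose members share specific terms
#' and are wired to be molecularly related. Defaults are the study
#' conditions used throughout the package's end-to-end checks: 60 terms in
#' 3 branches, 24 diseases in 4 clusters with within-cluster term overlap
#' 0.8.
#'
#' @param n_terms Total descriptor pool size.
#' @param n_branches Number of category branches (letters A, B, C, ...).
#' @param branch_overlap_fraction Fraction of terms carrying tree numbers in
#'   at least two branches.
#' @param max_parents Maximum number of parents a term may receive within a
#'   branch.
#' @param n_diseases Number of diseases in the corpus universe.
#' @param terms_per_disease Integer range `c(min, max)` of annotation terms
#'   drawn per disease.
#' @param n_clusters Number of planted disease clusters.
#' @param within_cluster_term_overlap Probability that a disease draws from
#'   its cluster's specific-term pool (its first draw is the cluster anchor
#'   term with this probability, so overlap 1 guarantees every
#'   within-cluster pair shares a term).
#' @param seed Integer seed; identical spec and seed give identical fixtures.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 60, n_branches = 3,
                         branch_overlap_fraction = 0.2, max_parents = 2,
                         n_diseases = 24, terms_per_disease = c(3, 6),
                         n_clusters = 4, within_cluster_term_overlap = 0.8,
                         seed = 1) {
  stopifnot(n_terms >= 1, n_branches >= 1, max_parents >= 1,
            n_diseases >= 1, n_clusters >= 1,
            length(terms_per_disease) == 2,
            terms_per_disease[1] >= 1,
            terms_per_disease[2] >= terms_per_disease[1],
            branch_overlap_fraction >= 0, branch_overlap_fraction <= 1,
            within_cluster_term_overlap >= 0,
            within_cluster_term_overlap <= 1)
  structure(
    list(n_terms = as.integer(n_terms), n_branches = as.integer(n_branches),
         branch_overlap_fraction = branch_overlap_fraction,
         max_parents = as.integer(max_parents),
         n_diseases = as.integer(n_diseases),
         terms_per_disease = as.integer(terms_per_disease),
         n_clusters = as.integer(n_clusters),
         within_cluster_term_overlap = within_cluster_term_overlap,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate random overlapping ontology branches
#'
#' Produces one DAG per branch over a shared term pool. A
#' `branch_overlap_fraction` of terms receive tree numbers in two or more
#' branches; within each branch terms attach under randomly chosen earlier
#' terms, and with `max_parents > 1` some terms receive additional tree
#' numbers (extra parents). Every branch is acyclic by construction and the
#' result is a pure function of the spec (all randomness flows from
#' `spec$seed`).
#'
#' @param spec A [fixture_spec()].
#' @return A list of `mesh_ontology` objects, one per branch.
#' @export
random_ontology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_shared <- round(spec$branch_overlap_fraction * spec$n_terms)
  if (n_shared > 0L && spec$n_branches < 2L) {
    abort("branch_overlap_fraction > 0 requires at least 2 branches.")
  }
  withr::with_seed(spec$seed, {
    terms <- sprintf("T%03d", seq_len(spec$n_terms))
    letters_used <- LETTERS[seq_len(spec$n_branches)]
    # membership: shared terms get >= 2 branches, the rest one each;
    # seed each branch with one exclusive term first when possible
    membership <- setNames(vector("list", spec$n_terms), terms)
    shared <- if (n_shared > 0L) sample(terms, n_shared) else character()
    solo <- setdiff(terms, shared)
    for (t in shared) {
      k <- if (spec$n_branches == 2L) 2L else sample(2:spec$n_branches, 1L)
      membership[[t]] <- sort(sample(letters_used, k))
    }
    for (i in seq_along(solo)) {
      membership[[solo[[i]]]] <-
        if (i <= spec$n_branches) letters_used[[i]]
        else sample(letters_used, 1L)
    }

    # one global order shared by all branches: a term only ever attaches
    # under terms earlier in this order, so the per-branch DAGs stay acyclic
    # after merging (cross-branch parent chains can never loop back)
    global_order <- sample(terms)
    rows <- list()
    for (br in letters_used) {
      members <- global_order[global_order %in%
                                terms[vapply(membership, function(m) br %in% m,
                                             TRUE)]]
      if (length(members) == 0L) next
      placed_codes <- character()   # primary code per placed term
      n_top <- 0L
      n_child <- 0L
      for (i in seq_along(members)) {
        t <- members[[i]]
        if (i == 1L || stats::runif(1) < 0.15) {
          n_top <- n_top + 1L
          code <- sprintf("%s%02d", br, n_top)
        } else {
          parent <- sample(placed_codes, 1L)
          n_child <- n_child + 1L
          code <- sprintf("%s.%03d", parent, n_child)
        }
        codes <- code
        if (spec$max_parents > 1L && i > 2L && stats::runif(1) < 0.3) {
          n_extra <- sample(seq_len(spec$max_parents - 1L), 1L)
          others <- setdiff(placed_codes, code)
          for (p in utils::head(sample(others), n_extra)) {
            n_child <- n_child + 1L
            codes <- c(codes, sprintf("%s.%03d", p, n_child))
          }
        }
        placed_codes <- c(placed_codes, code)
        names(placed_codes)[length(placed_codes)] <- t
        rows[[length(rows) + 1L]] <-
          tibble::tibble(term_id = t, name = paste("Term", t),
                         tree_number = codes)
      }
    }
    rows <- dplyr::bind_rows(rows)
    lapply(sort(unique(substr(rows$tree_number, 1L, 1L))), function(br) {
      ontology_from_rows(rows[substr(rows$tree_number, 1L, 1L) == br, ], br)
    })
  })
}

#' Plant a clustered disease corpus with molecular gold standards
#'
#' Diseases are split into clusters; each cluster owns an anchor term and a
#' pool of specific terms drawn from the merged ontology, disjoint across
#' clusters. A disease's first annotation draw is its cluster anchor with
#' probability `within_cluster_term_overlap` (otherwise a random term), and
#' the remaining draws come from the cluster pool with the same probability
#' (otherwise the global pool). Each disease carries one unique protein and
#' one unique gene plus a cluster gene; interactions connect all
#' same-cluster proteins, so gold-standard positives are exactly the
#' within-cluster pairs. All randomness is a pure function of
#' `(spec, branches)` through `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @param branches A list of `mesh_ontology` branches, as produced by
#'   [random_ontology()].
#' @return A list with `corpus` (an `annotation_corpus`), `labels` (tibble
#'   `disease_id`, `class`), `disease_genes`, `disease_proteins`,
#'   `interactions` (tibbles) and `merged` (the merged `mesh_ontology`).
#' @export
planted_corpus <- function(spec, branches) {
  stopifnot(inherits(spec, "fixture_spec"))
  merged <- merge_ontologies(branches)
  terms <- ontology_terms(merged)
  withr::with_seed(spec$seed + 1L, {
    diseases <- sprintf("D%03d", seq_len(spec$n_diseases))
    cluster <- rep(seq_len(spec$n_clusters), length.out = spec$n_diseases)
    pool_size <- max(2L, min(length(terms) %/% (2L * spec$n_clusters),
                             spec$terms_per_disease[[2]]))
    if (pool_size * spec$n_clusters > length(terms)) {
      abort("Infeasible spec: not enough terms for disjoint cluster pools.")
    }
    # cluster pools hold *specific* terms: rank descriptors by tree depth
    # (random tie-break) and carve the disjoint pools from the deepest ones,
    # so shared within-cluster terms carry high information content
    tn <- merged$tree_numbers
    depth <- tapply(nchar(gsub("[^.]", "", tn$tree_number)) + 1L,
                    tn$term_id, max)
    by_depth <- names(depth)[order(-depth, stats::runif(length(depth)))]
    specific <- utils::head(by_depth, pool_size * spec$n_clusters)
    specific <- sample(specific)
    pools <- lapply(seq_len(spec$n_clusters), function(k) {
      specific[seq.int((k - 1L) * pool_size + 1L, k * pool_size)]
    })
    # literature annotations also carry ubiquitous broad headings shared by
    # unrelated diseases; emulate them with a small pool of the shallowest
    # terms from which every disease draws, so they end up frequent (low IC)
    broad_pool <- utils::head(rev(by_depth), max(3L, spec$n_terms %/% 12L))
    n_broad_draws <- min(2L, length(broad_pool))
    anns <- lapply(seq_along(diseases), function(i) {
      k <- cluster[[i]]
      m_range <- seq.int(spec$terms_per_disease[[1]],
                         spec$terms_per_disease[[2]])
      m <- if (length(m_range) == 1L) m_range else sample(m_range, 1L)
      anchor <- pools[[k]][[1L]]
      first <- if (stats::runif(1) < spec$within_cluster_term_overlap) anchor
               else sample(terms, 1L)
      rest <- vapply(seq_len(m - 1L), function(j) {
        if (stats::runif(1) < spec$within_cluster_term_overlap) {
          sample(pools[[k]], 1L)
        } else {
          sample(terms, 1L)
        }
      }, "")
      broad <- sample(broad_pool, n_broad_draws)
      unique(c(first, rest, broad))
    })
    names(anns) <- diseases

    proteins <- setNames(paste0("P_", diseases), diseases)
    interactions <- dplyr::bind_rows(lapply(seq_len(spec$n_clusters),
                                            function(k) {
      members <- proteins[cluster == k]
      p <- all_unordered_pairs(members)
      names(p) <- c("protein_a", "protein_b")
      p
    }))
    list(
      corpus = annotation_corpus(anns, universe = diseases),
      labels = tibble::tibble(disease_id = diseases,
                              class = sprintf("cluster%02d", cluster)),
      disease_genes = dplyr::bind_rows(
        tibble::tibble(disease_id = diseases,
                       gene_id = sprintf("G_clust%02d", cluster)),
        tibble::tibble(disease_id = diseases,
                       gene_id = paste0("G_", diseases))
      ),
      disease_proteins = tibble::tibble(disease_id = diseases,
                                        protein_id = unname(proteins)),
      interactions = interactions,
      merged = merged
    )
  })
}
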