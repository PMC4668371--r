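#' MeSH-style term ontologies
#'
#' An ontology is a directed acyclic graph over descriptor terms. Each term
#' carries one or more *tree numbers* — dot-separated codes such as
#' `"A01.378.610"` whose first letter names the category branch (A = Anatomy,
#' C = Diseases, ...). The parent of a tree number is obtained by dropping its
#' last segment; a descriptor with several tree numbers therefore has several
#' parents, and descriptors placed in more than one branch are represented as
#' a single node, which is what links the branches into one structure when
#' they are merged. A synthetic root (with zero information content) sits
#' above all top-level codes so that every pair of terms has at least one
#' common ancestor.
#'
#' @name mesh_ontology
#' @seealso [read_mesh_xml()], [read_ontology_tsv()], [merge_ontologies()],
#'   [term_ancestors()], [branch_overlap()]
NULL

ROOT_ID <- "MESH:ROOT"

#' Build an ontology from (term_id, name, tree_number) rows
#'
#' This is the single construction path used by all readers and by
#' [merge_ontologies()]. Edges follow the drop-last-segment relation on tree
#' numbers restricted to the selected categories; a tree number whose parent
#' code is not owned by any selected descriptor is retargeted to the nearest
#' selected ancestor code, and failing that to the synthetic root. Tree
#' numbers whose first letter falls outside `categories` are dropped.
#'
#' @param rows A data frame with columns `term_id`, `name`, `tree_number`
#'   (one row per tree number).
#' @param categories Character vector of single-letter branch codes to keep.
#' @return An object of class `mesh_ontology`.
#' @export
ontology_from_rows <- function(rows, categories) {
  stopifnot(is.data.frame(rows),
            all(c("term_id", "name", "tree_number") %in% names(rows)))
  if (length(categories) == 0L) {
    abort("`categories` must contain at least one branch letter.")
  }
  categories <- sort(unique(as.character(categories)))

  rows <- tibble::tibble(
    term_id = as.character(rows$term_id),
    name = as.character(rows$name),
    tree_number = as.character(rows$tree_number)
  )
  dup <- duplicated(rows[, c("term_id", "tree_number")])
  if (any(dup)) {
    abort(paste0("Duplicate (term_id, tree_number) rows: ",
                 paste(unique(rows$term_id[dup]), collapse = ", ")))
  }
  rows <- rows[substr(rows$tree_number, 1L, 1L) %in% categories, ]
  if (nrow(rows) == 0L) {
    abort(paste0("No terms in requested categories {",
                 paste(categories, collapse = ","), "}."))
  }

  # one node per descriptor; conflicting names are corrupt input
  name_map <- unique(rows[, c("term_id", "name")])
  conflicts <- name_map$term_id[duplicated(name_map$term_id)]
  if (length(conflicts)) {
    abort(paste0("Conflicting names for term ids: ",
                 paste(unique(conflicts), collapse = ", ")))
  }

  code_owner <- setNames(rows$term_id, rows$tree_number)
  if (anyDuplicated(names(code_owner))) {
    abort("A tree number is owned by more than one descriptor.")
  }

  parent_of_code <- function(code, self_id) {
    # walk up the code prefix chain to the nearest selected owner that is
    # not the term itself; attach to the root when the chain runs out
    repeat {
      dot <- regexpr("\\.[^.]*$", code)
      if (dot < 0L) return(ROOT_ID)
      code <- substr(code, 1L, dot - 1L)
      owner <- unname(code_owner[code])
      if (!is.na(owner) && owner != self_id) return(owner)
    }
  }

  parent_id <- mapply(parent_of_code, rows$tree_number, rows$term_id,
                      USE.NAMES = FALSE)
  edges <- unique(data.frame(child = rows$term_id, parent = parent_id,
                             stringsAsFactors = FALSE))
  ids <- sort(unique(rows$term_id))
  parents <- lapply(split(edges$parent, edges$child), function(p) sort(unique(p)))
  parents <- parents[ids]
  names(parents) <- ids

  o <- structure(
    list(
      terms = dplyr::arrange(name_map, .data$term_id),
      tree_numbers = dplyr::arrange(rows[, c("term_id", "tree_number")],
                                    .data$term_id, .data$tree_number),
      parents = parents,
      categories = categories,
      root_id = ROOT_ID,
      anc_cache = new.env(parent = emptyenv())
    ),
    class = "mesh_ontology"
  )
  assert_acyclic(o)
  o
}

# Kahn topological sort over the parent relation; aborts on a cycle.
assert_acyclic <- function(o) {
  ids <- names(o$parents)
  indeg <- setNames(vapply(o$parents, function(p) sum(p != ROOT_ID), 0L), ids)
  children <- split(
    rep(ids, lengths(o$parents)),
    unlist(o$parents, use.names = FALSE)
  )
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[v]] %||% character()) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(ids)) {
    abort("Cycle detected in ontology parent relation (corrupt tree numbers).")
  }
  invisible(o)
}

#' @export
print.mesh_ontology <- function(x, ...) {
  cat(sprintf("<mesh_ontology> %d terms, %d tree numbers, branches {%s}\n",
              nrow(x$terms), nrow(x$tree_numbers),
              paste(x$categories, collapse = ",")))
  invisible(x)
}

#' Term ids of an ontology (excluding the synthetic root)
#' @param o A `mesh_ontology`.
#' @return Character vector of descriptor ids.
#' @export
ontology_terms <- function(o) {
  stopifnot(inherits(o, "mesh_ontology"))
  o$terms$term_id
}

#' @method tidy mesh_ontology
#' @export
tidy.mesh_ontology <- function(x, ...) {
  dplyr::left_join(x$tree_numbers, x$terms, by = "term_id")[,
    c("term_id", "name", "tree_number")] |> tibble::as_tibble()
}

#' Read an ontology from MeSH descriptor XML
#'
#' Parses the standard NLM descriptor distribution schema (`DescriptorRecord`
#' elements with `DescriptorUI`, `DescriptorName/String` and
#' `TreeNumberList/TreeNumber`) and keeps descriptors having at least one
#' tree number in the requested category branches. A descriptor present in
#' several requested branches becomes a single node.
#'
#' @param path Path to a MeSH descriptor XML file.
#' @param categories Character vector of branch letters (default the five
#'   high-coverage branches A, C, D, E, G).
#' @return A `mesh_ontology`.
#' @export
read_mesh_xml <- function(path, categories = c("A", "C", "D", "E", "G")) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("Malformed MeSH XML in '", path, "': ", conditionMessage(e)))
  })
  recs <- xml2::xml_find_all(doc, ".//DescriptorRecord")
  rows <- purrr::map_dfr(recs, function(rec) {
    ui <- xml2::xml_text(xml2::xml_find_first(rec, "./DescriptorUI"))
    nm <- xml2::xml_text(xml2::xml_find_first(rec, "./DescriptorName/String"))
    tn <- xml2::xml_text(xml2::xml_find_all(rec, "./TreeNumberList/TreeNumber"))
    if (is.na(ui) || ui == "" || is.na(nm)) {
      abort(paste0("Malformed DescriptorRecord (missing DescriptorUI or ",
                   "DescriptorName) near record '", ui, "'."))
    }
    if (length(tn) == 0L) return(NULL)
    tibble::tibble(term_id = ui, name = nm, tree_number = tn)
  })
  if (nrow(rows) == 0L ||
      !any(substr(rows$tree_number, 1L, 1L) %in% categories)) {
    abort(paste0("No terms in requested categories {",
                 paste(categories, collapse = ","), "}."))
  }
  ontology_from_rows(rows, categories)
}

#' Read / write the ontology TSV dialect
#'
#' The interchange dialect is a UTF-8 TSV with header
#' `term_id  name  tree_number`, one row per tree number. The writer emits
#' rows sorted by `(term_id, tree_number)` so that write–read round trips are
#' bit-exact.
#'
#' @param path File path.
#' @param categories Branch letters to keep; defaults to every letter present
#'   in the file.
#' @return `read_ontology_tsv()` returns a `mesh_ontology`;
#'   `write_ontology_tsv()` returns `path` invisibly.
#' @export
read_ontology_tsv <- function(path, categories = NULL) {
  rows <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (!all(c("term_id", "name", "tree_number") %in% names(rows))) {
    abort("Ontology TSV must have columns term_id, name, tree_number.")
  }
  if (is.null(categories)) {
    categories <- sort(unique(substr(rows$tree_number, 1L, 1L)))
  }
  ontology_from_rows(rows, categories)
}

#' @rdname read_ontology_tsv
#' @param o A `mesh_ontology`.
#' @export
write_ontology_tsv <- function(o, path) {
  stopifnot(inherits(o, "mesh_ontology"))
  readr::write_tsv(tidy(o), path, progress = FALSE)
  invisible(path)
}

#' Merge category branches into one ontological structure
#'
#' Nodes are unioned by descriptor id (a descriptor appearing in several
#' branches stays a single node), parent sets are unioned, and one synthetic
#' root is placed above every former per-branch top-level term. Terms shared
#' between branches create paths linking the branches into a single DAG, so
#' one similarity score can be computed per disease pair instead of one per
#' branch.
#'
#' @param branches A list of `mesh_ontology` objects (or a single one).
#' @return A `mesh_ontology` over the union of the branches.
#' @export
merge_ontologies <- function(branches) {
  if (inherits(branches, "mesh_ontology")) branches <- list(branches)
  stopifnot(length(branches) >= 1L,
            all(vapply(branches, inherits, TRUE, "mesh_ontology")))
  names_all <- dplyr::distinct(purrr::map_dfr(branches, ~ .x$terms))
  conflicts <- unique(names_all$term_id[duplicated(names_all$term_id)])
  if (length(conflicts)) {
    abort(paste0("Conflicting names for term ids across branches: ",
                 paste(conflicts, collapse = ", ")))
  }
  rows <- dplyr::distinct(purrr::map_dfr(branches, tidy))
  cats <- sort(unique(unlist(lapply(branches, function(b) b$categories))))
  ontology_from_rows(rows, cats)
}

#' Ancestors of a term (reflexive, including the root)
#'
#' Implements the True Path Rule closure: the returned set contains `t`
#' itself, every term reachable by repeatedly following parents, and the
#' synthetic root. Results are memoised per ontology.
#'
#' @param o A `mesh_ontology`.
#' @param t A term id present in `o` (or the root id).
#' @return Sorted character vector of term ids.
#' @export
term_ancestors <- function(o, t) {
  stopifnot(inherits(o, "mesh_ontology"))
  if (t == o$root_id) return(o$root_id)
  if (is.null(o$parents[[t]])) {
    abort(paste0("Unknown term id '", t, "'."))
  }
  anc_of(o, t)
}

anc_of <- function(o, t) {
  cached <- o$anc_cache[[t]]
  if (!is.null(cached)) return(cached)
  ps <- o$parents[[t]]
  up <- unlist(lapply(ps[ps != o$root_id], anc_of, o = o), use.names = FALSE)
  res <- sort(unique(c(t, o$root_id, ps, up)))
  assign(t, res, envir = o$anc_cache)
  res
}

#' Pairwise overlap between ontology branches
#'
#' Quantifies how strongly category branches share descriptors: for every
#' pair of branches it reports the number of shared terms and the Jaccard
#' coefficient of their term sets (the synthetic root is excluded). Shared
#' terms are what allows [merge_ontologies()] to link the branches into a
#' single structure.
#'
#' @param branches A list of at least two `mesh_ontology` objects.
#' @return A tibble with one row per ordered branch pair (so it pivots
#'   directly to a symmetric matrix): `branch_a`, `branch_b`, `n_shared`,
#'   `n_union`, `jaccard`. An empty branch has Jaccard 0 against everything,
#'   including itself.
#' @export
branch_overlap <- function(branches) {
  stopifnot(is.list(branches), length(branches) >= 2L,
            all(vapply(branches, inherits, TRUE, "mesh_ontology")))
  labels <- vapply(branches, function(b) paste(b$categories, collapse = ""), "")
  if (anyDuplicated(labels)) {
    labels <- paste0(labels, ".", seq_along(labels))
  }
  sets <- lapply(branches, ontology_terms)
  grid <- expand.grid(i = seq_along(branches), j = seq_along(branches))
  res <- purrr::pmap_dfr(grid, function(i, j) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    tibble::tibble(
      branch_a = labels[[i]], branch_b = labels[[j]],
      n_shared = inter, n_union = uni,
      jaccard = if (uni == 0L) 0 else inter / uni
    )
  })
  structure(dplyr::arrange(res, .data$branch_a, .data$branch_b),
            class = c("branch_overlap", class(res)))
}

#' @method autoplot branch_overlap
#' @export
autoplot.branch_overlap <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$branch_a, y = .data$branch_b,
                               fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_shared), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard",
                  title = "Branch overlap (tile label = shared terms)") +
    ggplot2::theme_minimal()
}
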