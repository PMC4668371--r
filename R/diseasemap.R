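#' Convert similarities to a distance matrix
#'
#' t-SNE and related embeddings need dissimilarities. The default transform
#' is linear: `distance(a, b) = max_score - score(a, b)` with a zero
#' diagonal; pairs with an undefined similarity are assigned `max_score`
#' (maximally distant). A monotone alternative `1 / (1 + score)` is
#' available for unbounded score scales.
#'
#' @param result A `similarity_result` with at least one scored pair.
#' @param method `"linear"` (default) or `"inverse"`.
#' @return A symmetric numeric matrix with disease ids as dimnames.
#' @export
similarity_to_distance <- function(result, method = c("linear", "inverse")) {
  method <- match.arg(method)
  stopifnot(inherits(result, "similarity_result"))
  sc <- result$scores
  if (nrow(sc) == 0L) abort("No scored pairs in result.")
  ids <- sort(unique(c(sc$disease_a, sc$disease_b,
                       result$undefined_pairs$disease_a,
                       result$undefined_pairs$disease_b)))
  n <- length(ids)
  max_score <- max(sc$score)
  fill <- if (method == "linear") max_score else 1 / (1 + 0)
  D <- matrix(fill, n, n, dimnames = list(ids, ids))
  i <- match(sc$disease_a, ids)
  j <- match(sc$disease_b, ids)
  d <- if (method == "linear") max_score - sc$score else 1 / (1 + sc$score)
  D[cbind(i, j)] <- d
  D[cbind(j, i)] <- d
  diag(D) <- 0
  D
}

#' 3D t-SNE embedding of the disease similarity space
#'
#' Embeds diseases into three dimensions with t-SNE on a precomputed
#' distance matrix. Defaults follow common practice for disease maps:
#' perplexity 30 and 50 dimensions for the PCA-style pre-processing step
#' (implemented as classical MDS of the distance matrix, since the input is
#' a distance and not a feature matrix; when `pca_dims` is at least the
#' number of points minus one, the distances are passed to t-SNE directly).
#' The optimisation is delegated to \pkg{Rtsne} in exact mode and is
#' deterministic at a fixed seed.
#'
#' @param distances Symmetric distance matrix with disease-id dimnames (as
#'   from [similarity_to_distance()]).
#' @param perplexity t-SNE perplexity; must be below the number of points
#'   (default 30).
#' @param pca_dims Target dimensionality of the pre-reduction (default 50).
#' @param seed Integer seed controlling the embedding initialisation.
#' @param max_iter Number of gradient-descent iterations (default 1000).
#' @return A tibble `disease_id`, `x`, `y`, `z`.
#' @export
embed_3d <- function(distances, perplexity = 30, pca_dims = 50, seed = 1,
                     max_iter = 1000) {
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
  n <- nrow(distances)
  if (n < 4L) abort("At least 4 diseases are required for a 3D embedding.")
  if (perplexity >= n) {
    abort(sprintf("perplexity (%g) must be smaller than the number of points (%d).",
                  perplexity, n))
  }
  if (3 * perplexity > n - 1) {
    perplexity <- max(1, floor((n - 1) / 3))
    warn(sprintf("perplexity too large for %d points; lowered to %g.",
                 n, perplexity))
  }
  ids <- rownames(distances) %||% as.character(seq_len(n))
  fit <- withr::with_seed(seed, {
    if (pca_dims < n - 1L) {
      X <- stats::cmdscale(stats::as.dist(distances), k = pca_dims)
      Rtsne::Rtsne(X, dims = 3, perplexity = perplexity, theta = 0,
                   pca = FALSE, max_iter = max_iter)
    } else {
      Rtsne::Rtsne(stats::as.dist(distances), dims = 3,
                   perplexity = perplexity, theta = 0, is_distance = TRUE,
                   max_iter = max_iter)
    }
  })
  tibble::tibble(disease_id = ids, x = fit$Y[, 1], y = fit$Y[, 2],
                 z = fit$Y[, 3])
}

#' Plot a 2D projection of an embedding coloured by class
#'
#' @param embedding Tibble from [embed_3d()].
#' @param labels Optional tibble `disease_id`, `class`.
#' @return A ggplot of the (x, y) projection.
#' @export
plot_embedding <- function(embedding, labels = NULL) {
  df <- embedding
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, labels, by = "disease_id")
  } else {
    df$class <- "unlabelled"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = "Disease map (t-SNE, first two of three dimensions)",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Class-level mean similarity matrix
#'
#' For disease classes (physiological-system categories in the style of Goh
#' et al.), entry (x, y) is the mean similarity over scored pairs with one
#' disease in class x and the other in class y; the diagonal uses unordered
#' within-class pairs (no self-pairs). Only the `top_k_classes` most
#' populous classes are kept. Also reports mean intra-class vs inter-class
#' similarity with a Welch t-test between the two pools of pair scores.
#'
#' @param result A `similarity_result`.
#' @param labels Tibble `disease_id`, `class` (unlabelled diseases are
#'   excluded).
#' @param top_k_classes Number of most populous classes to keep (default 10).
#' @return An object of class `class_heatmap`: list with `means` (symmetric
#'   matrix, `NA` where a class pair has no scored pairs), `intra_mean`,
#'   `inter_mean`, `t_statistic`, `p_value`, `class_sizes`.
#' @export
class_heatmap <- function(result, labels, top_k_classes = 10) {
  stopifnot(inherits(result, "similarity_result"),
            all(c("disease_id", "class") %in% names(labels)))
  lab <- setNames(as.character(labels$class), as.character(labels$disease_id))
  sc <- result$scores
  sc <- sc[sc$disease_a %in% names(lab) & sc$disease_b %in% names(lab), ]
  sizes <- sort(table(lab[unique(c(sc$disease_a, sc$disease_b))]),
                decreasing = TRUE)
  eligible <- names(sizes)[sizes >= 2L]
  if (length(eligible) < 2L) {
    abort("Need at least 2 classes with at least 2 diseases each.")
  }
  classes <- utils::head(names(sizes)[names(sizes) %in% eligible],
                         top_k_classes)
  classes <- sort(classes)
  ca <- lab[sc$disease_a]
  cb <- lab[sc$disease_b]
  keep <- ca %in% classes & cb %in% classes
  sc <- sc[keep, ]
  ca <- ca[keep]
  cb <- cb[keep]
  k <- length(classes)
  means <- matrix(NA_real_, k, k, dimnames = list(classes, classes))
  for (x in classes) for (y in classes) {
    if (x > y) next
    sel <- (ca == x & cb == y) | (ca == y & cb == x)
    if (any(sel)) means[x, y] <- means[y, x] <- mean(sc$score[sel])
  }
  intra <- sc$score[ca == cb]
  inter <- sc$score[ca != cb]
  tt <- if (length(intra) >= 2L && length(inter) >= 2L) {
    tryCatch(stats::t.test(intra, inter),
             error = function(e) NULL)  # constant scores have no t statistic
  } else NULL
  structure(
    list(means = means,
         intra_mean = if (length(intra)) mean(intra) else NA_real_,
         inter_mean = if (length(inter)) mean(inter) else NA_real_,
         t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
         p_value = if (is.null(tt)) NA_real_ else tt$p.value,
         class_sizes = sizes[classes]),
    class = "class_heatmap"
  )
}

#' @export
print.class_heatmap <- function(x, ...) {
  cat(sprintf("<class_heatmap> %d classes; intra-class mean %.3f vs inter-class mean %.3f (Welch t=%.2f, p=%.3g)\n",
              ncol(x$means), x$intra_mean, x$inter_mean, x$t_statistic,
              x$p_value))
  invisible(x)
}

#' @method tidy class_heatmap
#' @export
tidy.class_heatmap <- function(x, ...) {
  m <- x$means
  tibble::tibble(
    class_a = rep(rownames(m), times = ncol(m)),
    class_b = rep(colnames(m), each = nrow(m)),
    mean_score = as.vector(m)
  )
}

#' @method glance class_heatmap
#' @export
glance.class_heatmap <- function(x, ...) {
  tibble::tibble(n_classes = ncol(x$means), intra_mean = x$intra_mean,
                 inter_mean = x$inter_mean, t_statistic = x$t_statistic,
                 p_value = x$p_value)
}

#' @param object A `class_heatmap`.
#' @param cap Colour-scale ceiling applied in the plot only (the stored
#'   matrix is never clipped); `NULL` disables clipping.
#' @param ... Unused.
#' @rdname class_heatmap
#' @method autoplot class_heatmap
#' @export
autoplot.class_heatmap <- function(object, cap = 2, ...) {
  df <- tidy(object)
  if (!is.null(cap)) df$mean_score <- pmin(df$mean_score, cap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class_a, y = .data$class_b,
                                   fill = .data$mean_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean\nsimilarity",
                  title = "Mean similarity between disease classes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
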