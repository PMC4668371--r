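# Independent brute-force reference implementations. These deliberately use
# naive algorithms (per-query recursive closures, exhaustive double loops,
# direct set algebra) and never touch the package's caches, so agreement
# with the optimised code paths is meaningful.

oracle_guard <- function(o, corpus) {
  if (length(ontology_terms(o)) > 60 || length(corpus$universe) > 25) {
    stop("oracle suite restricted to <= 60 terms and <= 25 diseases")
  }
}

# reflexive-transitive parent closure by plain recursion, no memoisation
oracle_ancestors <- function(o, t) {
  if (t == o$root_id) return(o$root_id)
  out <- c(t, o$root_id)
  for (p in o$parents[[t]]) {
    if (p != o$root_id) out <- c(out, oracle_ancestors(o, p))
  }
  sort(unique(out))
}

# per-term recount over all diseases and full ancestor closures
oracle_ic <- function(o, corpus) {
  keep <- ontology_terms(o)
  ann <- lapply(corpus$annotations, function(ts) intersect(ts, keep))
  ann <- ann[lengths(ann) > 0]
  n <- length(ann)
  stopifnot(n > 0)
  candidates <- c(keep, o$root_id)
  counts <- vapply(candidates, function(t) {
    sum(vapply(ann, function(ts) {
      any(vapply(ts, function(t2) t %in% oracle_ancestors(o, t2), TRUE))
    }, TRUE))
  }, 0)
  counts <- counts[counts > 0]
  list(ic = -log(counts / n), counts = counts, n = n)
}

oracle_resnik_term <- function(o, oic, t1, t2) {
  common <- intersect(oracle_ancestors(o, t1), oracle_ancestors(o, t2))
  vals <- oic$ic[intersect(common, names(oic$ic))]
  if (length(vals) == 0) 0 else max(vals)
}

oracle_lin_term <- function(o, oic, t1, t2) {
  denom <- oic$ic[[t1]] + oic$ic[[t2]]
  if (denom == 0) return(1)
  2 * oracle_resnik_term(o, oic, t1, t2) / denom
}

# exhaustive double loop over every term pair with finite IC
oracle_jiang_M <- function(o, oic) {
  ts <- names(oic$ic)
  M <- 0
  for (i in seq_along(ts)) for (j in i:length(ts)) {
    d <- oic$ic[[ts[i]]] + oic$ic[[ts[j]]] -
      2 * oracle_resnik_term(o, oic, ts[i], ts[j])
    if (d > M) M <- d
  }
  M
}

oracle_jiang_term <- function(o, oic, t1, t2, M) {
  if (M == 0) return(1)
  1 - (oic$ic[[t1]] + oic$ic[[t2]] -
         2 * oracle_resnik_term(o, oic, t1, t2)) / M
}

# disease-level max over the full cross product of usable terms
oracle_disease_sim <- function(a, b, corpus, o, oic, term_fun, ...) {
  ta <- intersect(corpus$annotations[[a]], names(oic$ic))
  tb <- intersect(corpus$annotations[[b]], names(oic$ic))
  if (length(ta) == 0 || length(tb) == 0) return(NA_real_)
  best <- -Inf
  for (t1 in ta) for (t2 in tb) {
    best <- max(best, term_fun(o, oic, t1, t2, ...))
  }
  best
}

oracle_expand <- function(d, corpus, o) {
  ts <- intersect(corpus$annotations[[d]], ontology_terms(o))
  if (length(ts) == 0) return(character())
  sort(unique(unlist(lapply(ts, oracle_ancestors, o = o))))
}

oracle_simui <- function(a, b, corpus, o) {
  ua <- oracle_expand(a, corpus, o)
  ub <- oracle_expand(b, corpus, o)
  if (length(ua) == 0 || length(ub) == 0) return(NA_real_)
  length(intersect(ua, ub)) / length(union(ua, ub))
}

oracle_simgic <- function(a, b, corpus, o, oic) {
  ua <- oracle_expand(a, corpus, o)
  ub <- oracle_expand(b, corpus, o)
  if (length(ua) == 0 || length(ub) == 0) return(NA_real_)
  wsum <- function(ts) sum(oic$ic[intersect(ts, names(oic$ic))])
  denom <- wsum(union(ua, ub))
  if (denom == 0) return(1)
  wsum(intersect(ua, ub)) / denom
}

oracle_overlap <- function(a, b, corpus, kind) {
  A <- corpus$annotations[[a]]
  B <- corpus$annotations[[b]]
  if (length(A) == 0 || length(B) == 0) return(NA_real_)
  ni <- length(intersect(A, B))
  switch(kind,
         jaccard = ni / length(union(A, B)),
         dice = 2 * ni / (length(A) + length(B)),
         overlap = ni / min(length(A), length(B)),
         num_common = ni)
}

# reference scores for every measure over every unordered disease pair
oracle_suite <- function(o, corpus) {
  oracle_guard(o, corpus)
  oic <- oracle_ic(o, corpus)
  M <- oracle_jiang_M(o, oic)
  ds <- sort(corpus$universe)
  pairs <- t(utils::combn(ds, 2))
  score <- function(fun) {
    vapply(seq_len(nrow(pairs)), function(k) fun(pairs[k, 1], pairs[k, 2]),
           numeric(1))
  }
  tibble::tibble(
    disease_a = pairs[, 1], disease_b = pairs[, 2],
    resnik = score(function(a, b)
      oracle_disease_sim(a, b, corpus, o, oic, oracle_resnik_term)),
    lin = score(function(a, b)
      oracle_disease_sim(a, b, corpus, o, oic, oracle_lin_term)),
    jiang = score(function(a, b)
      oracle_disease_sim(a, b, corpus, o, oic, oracle_jiang_term, M = M)),
    simui = score(function(a, b) oracle_simui(a, b, corpus, o)),
    simgic = score(function(a, b) oracle_simgic(a, b, corpus, o, oic)),
    jaccard = score(function(a, b) oracle_overlap(a, b, corpus, "jaccard")),
    dice = score(function(a, b) oracle_overlap(a, b, corpus, "dice")),
    overlap = score(function(a, b) oracle_overlap(a, b, corpus, "overlap")),
    num_common = score(function(a, b)
      oracle_overlap(a, b, corpus, "num_common"))
  )
}

# AUC by trapezoidal integration of the empirical ROC curve (threshold
# sweep over unique scores), independent of the rank-statistic route
oracle_auc_trapezoid <- function(score, is_positive) {
  stopifnot(any(is_positive), any(!is_positive))
  ths <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(ths, function(t) mean(score[is_positive] >= t), 0)
  fpr <- vapply(ths, function(t) mean(score[!is_positive] >= t), 0)
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# rule-by-rule gold-standard builders (exhaustive triple loops)
oracle_ppi_positives <- function(dp, interactions) {
  ds <- sort(names(dp))
  ia <- paste(pmin(interactions$protein_a, interactions$protein_b),
              pmax(interactions$protein_a, interactions$protein_b))
  out <- character()
  for (i in seq_along(ds)) for (j in seq_along(ds)) {
    if (i >= j) next
    hit <- FALSE
    for (p in dp[[ds[i]]]) for (q in dp[[ds[j]]]) {
      if (paste(min(p, q), max(p, q)) %in% ia) hit <- TRUE
    }
    if (hit) out <- c(out, paste(ds[i], ds[j]))
  }
  out
}

oracle_pfam_positives <- function(dp, ps, mesh_names) {
  ds <- sort(names(dp))
  sigs <- lapply(dp, function(prots)
    sort(unique(unlist(ps[intersect(prots, names(ps))]))))
  out <- character()
  for (i in seq_along(ds)) for (j in seq_along(ds)) {
    if (i >= j) next
    shared <- intersect(sigs[[ds[i]]], sigs[[ds[j]]])
    if (length(shared) == 0) next
    if (any(tolower(shared) %in% tolower(mesh_names))) next
    if (identical(sort(dp[[ds[i]]]), sort(dp[[ds[j]]]))) next
    out <- c(out, paste(ds[i], ds[j]))
  }
  out
}

oracle_seqsim_positives <- function(dp, evalues, threshold = 1e-6) {
  ds <- sort(names(dp))
  good <- evalues[evalues$evalue <= threshold, ]
  keys <- c(paste(good$protein_a, good$protein_b),
            paste(good$protein_b, good$protein_a))
  out <- character()
  for (i in seq_along(ds)) for (j in seq_along(ds)) {
    if (i >= j) next
    if (identical(sort(dp[[ds[i]]]), sort(dp[[ds[j]]]))) next
    hit <- FALSE
    for (p in dp[[ds[i]]]) for (q in dp[[ds[j]]]) {
      if (paste(p, q) %in% keys) hit <- TRUE
    }
    if (hit) out <- c(out, paste(ds[i], ds[j]))
  }
  out
}
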