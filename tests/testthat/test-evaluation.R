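make_result <- function(scores_tbl, measure = "resnik") {
  meshsim:::new_similarity_result(
    scores_tbl,
    tibble::tibble(disease_a = character(), disease_b = character()),
    measure = measure, ontology_tag = "test"
  )
}

test_that("PPI gold standard relates diseases whose proteins interact", {
  dp <- tibble::tibble(disease_id = c("d1", "d2", "d3"),
                       protein_id = c("P1", "P2", "P3"))
  ia <- tibble::tibble(protein_a = "P1", protein_b = "P2")
  gold <- build_ppi_dataset(dp, ia)
  expect_equal(gold$positives,
               tibble::tibble(disease_a = "d1", disease_b = "d2"))
  expect_setequal(gold$eligible, c("d1", "d2", "d3"))

  none <- build_ppi_dataset(dp, ia[0, ])
  expect_equal(nrow(none$positives), 0)

  # a self-interaction relates two diseases sharing that protein
  dp2 <- tibble::tibble(disease_id = c("d1", "d2"), protein_id = c("P1", "P1"))
  self <- build_ppi_dataset(dp2, tibble::tibble(protein_a = "P1",
                                                protein_b = "P1"))
  expect_equal(nrow(self$positives), 1)
})

test_that("PPI builder matches an exhaustive triple loop on random fixtures", {
  for (seed in 1:4) {
    set.seed(seed)
    ds <- paste0("d", 1:8)
    prots <- paste0("P", 1:10)
    dp_tbl <- tibble::tibble(
      disease_id = rep(ds, each = 2),
      protein_id = sample(prots, 16, replace = TRUE)
    ) |> dplyr::distinct()
    ia <- tibble::tibble(protein_a = sample(prots, 6, replace = TRUE),
                         protein_b = sample(prots, 6, replace = TRUE))
    gold <- build_ppi_dataset(dp_tbl, ia)
    dp <- meshsim:::as_id_sets(dp_tbl, "disease_id", "protein_id")
    expect_setequal(paste(gold$positives$disease_a, gold$positives$disease_b),
                    oracle_ppi_positives(dp, ia))
  }
})

test_that("Pfam builder applies the name-match and identical-protein exclusions", {
  dp <- tibble::tibble(disease_id = c("d1", "d2", "d3", "d4"),
                       protein_id = c("P1", "P2", "P3", "P1"))
  ps <- tibble::tibble(protein_id = c("P1", "P2", "P3"),
                       signature = c("Kinase", "Kinase", "Zinc finger"))
  # shared signature matching a MeSH name (case-insensitive) is excluded
  gold <- build_pfam_dataset(dp, ps, mesh_names = c("kinase"))
  expect_equal(nrow(gold$positives), 0)
  # without the banned name the share counts, but identical protein sets
  # (d1, d4) remain excluded
  gold2 <- build_pfam_dataset(dp, ps, mesh_names = character())
  keys <- paste(gold2$positives$disease_a, gold2$positives$disease_b)
  expect_true("d1 d2" %in% keys)
  expect_false("d1 d4" %in% keys)
  expect_true("d2 d4" %in% keys)  # same signature via different proteins

  for (seed in 1:4) {
    set.seed(seed)
    ds <- paste0("d", 1:7)
    dp_tbl <- tibble::tibble(disease_id = rep(ds, each = 2),
                             protein_id = sample(paste0("P", 1:8), 14,
                                                 replace = TRUE)) |>
      dplyr::distinct()
    ps_tbl <- tibble::tibble(protein_id = sample(paste0("P", 1:8), 10,
                                                 replace = TRUE),
                             signature = sample(c("SigA", "SigB", "Kinase"),
                                                10, replace = TRUE)) |>
      dplyr::distinct()
    gold <- build_pfam_dataset(dp_tbl, ps_tbl, mesh_names = "KINASE")
    dp <- meshsim:::as_id_sets(dp_tbl, "disease_id", "protein_id")
    ps <- meshsim:::as_id_sets(ps_tbl, "protein_id", "signature")
    expect_setequal(paste(gold$positives$disease_a, gold$positives$disease_b),
                    oracle_pfam_positives(dp, ps, "KINASE"))
  }
})

test_that("sequence-similarity builder uses an inclusive e-value threshold", {
  dp <- tibble::tibble(disease_id = c("d1", "d2", "d3"),
                       protein_id = c("P1", "P2", "P3"))
  ev <- tibble::tibble(protein_a = c("P1", "P1"), protein_b = c("P2", "P3"),
                       evalue = c(1e-6, 1e-5))
  gold <- build_seqsim_dataset(dp, ev)
  keys <- paste(gold$positives$disease_a, gold$positives$disease_b)
  expect_true("d1 d2" %in% keys)   # exactly at the threshold counts
  expect_false("d1 d3" %in% keys)  # above the threshold does not

  for (seed in 1:4) {
    set.seed(seed)
    dp_tbl <- tibble::tibble(disease_id = rep(paste0("d", 1:6), each = 2),
                             protein_id = sample(paste0("P", 1:7), 12,
                                                 replace = TRUE)) |>
      dplyr::distinct()
    ev_tbl <- tibble::tibble(
      protein_a = sample(paste0("P", 1:7), 8, replace = TRUE),
      protein_b = sample(paste0("P", 1:7), 8, replace = TRUE),
      evalue = 10^sample(c(-8, -6, -4), 8, replace = TRUE)
    )
    gold <- build_seqsim_dataset(dp_tbl, ev_tbl)
    dp <- meshsim:::as_id_sets(dp_tbl, "disease_id", "protein_id")
    expect_setequal(paste(gold$positives$disease_a, gold$positives$disease_b),
                    oracle_seqsim_positives(dp, ev_tbl))
  }
})

test_that("dataset builders are insensitive to input row order", {
  set.seed(99)
  dp <- tibble::tibble(disease_id = rep(paste0("d", 1:6), each = 2),
                       protein_id = sample(paste0("P", 1:6), 12,
                                           replace = TRUE)) |>
    dplyr::distinct()
  ia <- tibble::tibble(protein_a = sample(paste0("P", 1:6), 5),
                       protein_b = sample(paste0("P", 1:6), 5))
  a <- build_ppi_dataset(dp, ia)
  b <- build_ppi_dataset(dp[sample(nrow(dp)), ], ia[sample(nrow(ia)), ])
  expect_identical(a$positives, b$positives)
  expect_identical(a$eligible, b$eligible)
})

test_that("rank-statistic AUC behaves at its fixed points", {
  ds <- paste0("d", 1:5)
  pairs <- meshsim:::all_unordered_pairs(ds)
  pos <- pairs[1:3, ]
  gold <- meshsim:::new_relationship_dataset(pos, ds, "custom")
  # perfect separation
  res <- make_result(dplyr::mutate(pairs, score = c(9, 8, 7, 1, 2, 3, 1, 2, 3, 1)))
  expect_equal(roc_auc(res, gold)$auc, 1.0)
  # constant scores: average ranks force 0.5
  res_const <- make_result(dplyr::mutate(pairs, score = 5))
  expect_equal(roc_auc(res_const, gold)$auc, 0.5)
  # degenerate class errors name the class
  all_pos <- meshsim:::new_relationship_dataset(pairs, ds, "custom")
  expect_error(roc_auc(res, all_pos), "negative")
  none_pos <- meshsim:::new_relationship_dataset(pairs[0, ], ds, "custom")
  expect_error(roc_auc(res, none_pos), "positive")
})

test_that("rank AUC equals trapezoidal ROC integration and standard identities", {
  set.seed(42)
  ds <- paste0("d", 1:21)                       # 210 pairs
  pairs <- meshsim:::all_unordered_pairs(ds)
  n <- nrow(pairs)
  labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.3, 0.7))
  score <- round(rnorm(n, mean = ifelse(labels, 1, 0)), 1)  # with ties
  gold <- meshsim:::new_relationship_dataset(pairs[labels, ], ds, "custom")
  res <- make_result(dplyr::mutate(pairs, score = score))
  auc <- roc_auc(res, gold)$auc
  expect_equal(auc, oracle_auc_trapezoid(score, labels), tolerance = 1e-12)
  # pROC as an additional independent reference
  expect_equal(auc,
               as.numeric(pROC::auc(pROC::roc(labels, score, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  # invariant under strictly increasing transforms
  res_exp <- make_result(dplyr::mutate(pairs, score = exp(score)))
  expect_equal(roc_auc(res_exp, gold)$auc, auc, tolerance = 1e-12)
  # swapping the labels maps AUC to 1 - AUC
  gold_swap <- meshsim:::new_relationship_dataset(pairs[!labels, ], ds, "custom")
  expect_equal(roc_auc(res, gold_swap)$auc, 1 - auc, tolerance = 1e-12)
  # undefined pairs are dropped from both classes
  res_holes <- make_result(dplyr::mutate(pairs, score = score)[-(1:20), ])
  expect_equal(roc_auc(res_holes, gold)$auc,
               oracle_auc_trapezoid(score[-(1:20)], labels[-(1:20)]),
               tolerance = 1e-12)
})

test_that("the composite score is coverage plus the sum of dataset AUCs", {
  case <- rand_case(8)
  res <- all_pairs(case$corpus, case$merged, case$ict, "resnik")
  gold <- build_ppi_dataset(case$fx$disease_proteins, case$fx$interactions)
  rep1 <- evaluate_measure(res, list(gold), case$fx$corpus, case$merged)
  expect_equal(rep1$composite, rep1$coverage + sum(rep1$aucs$auc))
  # no datasets: composite reduces to coverage
  rep0 <- evaluate_measure(res, list(), case$fx$corpus, case$merged)
  expect_equal(rep0$composite, rep0$coverage)
  # three perfectly separated datasets + full coverage gives composite 4
  sc <- res$scores
  top <- sc[order(-sc$score), ][1:10, c("disease_a", "disease_b")]
  perfect <- meshsim:::new_relationship_dataset(top, case$corpus$universe, "ppi")
  sep <- make_result(dplyr::mutate(
    meshsim:::all_unordered_pairs(case$corpus$universe),
    score = as.numeric(paste(disease_a, disease_b) %in%
                         paste(top$disease_a, top$disease_b))))
  rep4 <- evaluate_measure(sep, list(perfect, perfect, perfect),
                           case$fx$corpus, case$merged)
  expect_equal(rep4$composite, 3 + corpus_coverage(case$fx$corpus, case$merged))
  g <- glance(rep4)
  expect_equal(g$composite, rep4$composite)
})

test_that("shared-gene pairs are located within the overall score distribution", {
  ds <- paste0("d", sprintf("%02d", 1:30))
  pairs <- meshsim:::all_unordered_pairs(ds)
  set.seed(11)
  sc <- dplyr::mutate(pairs, score = runif(nrow(pairs)))
  res <- make_result(sc)
  # shared-gene pairs holding the maximum score: fraction at 99th is 1
  top <- sc[which.max(sc$score), ]
  genes_top <- tibble::tibble(
    disease_id = c(top$disease_a, top$disease_b),
    gene_id = "G1")
  sg_top <- shared_gene_analysis(res, genes_top)
  expect_equal(sg_top$fraction_at_99th, 1.0)
  expect_equal(max(sg_top$shared$percentile), 100)

  # the percentile of the global maximum is the 100th
  expect_equal(sg_top$shared$percentile[[which.max(sg_top$shared$score)]], 100)

  expect_error(shared_gene_analysis(res, tibble::tibble(
    disease_id = "d01", gene_id = "G9")), "shares a gene")
})

test_that("uniformly drawn shared-gene pairs sit near the 1% tail rate", {
  # simulation oracle: wire genes so that a random ~10% of pairs share one,
  # with scores independent of gene sharing
  set.seed(23)
  ds <- paste0("d", sprintf("%02d", 1:40))
  pairs <- meshsim:::all_unordered_pairs(ds)      # 780 pairs
  res <- make_result(dplyr::mutate(pairs, score = runif(nrow(pairs))))
  picked <- pairs[sample(nrow(pairs), 80), ]
  genes <- tibble::tibble(
    disease_id = c(picked$disease_a, picked$disease_b),
    gene_id = rep(paste0("G", seq_len(nrow(picked))), 2))
  sg <- shared_gene_analysis(res, genes)
  # binomial(n ~ 80, p = 0.01): the observed fraction stays below ~6%
  expect_lt(sg$fraction_at_99th, 0.06)
  expect_gt(mean(sg$shared$percentile), 30)  # not systematically extreme
})

test_that("top-percent table keeps boundary ties and joins proteins", {
  ds <- paste0("d", sprintf("%02d", 1:15))
  pairs <- meshsim:::all_unordered_pairs(ds)[1:100, ]
  set.seed(5)
  sc <- dplyr::mutate(pairs, score = sample(1:100))
  res <- make_result(sc)
  top5 <- top_percent_table(res, 0.05)
  # naive sort-and-slice oracle with tie keeping
  cut <- stats::quantile(sc$score, 0.95, type = 7, names = FALSE)
  expect_equal(nrow(top5), sum(sc$score >= cut))
  expect_equal(top5$score, sort(sc$score[sc$score >= cut], decreasing = TRUE))
  expect_equal(nrow(top_percent_table(res, 1.0)), 100)

  dp <- tibble::tibble(disease_id = top5$disease_a[[1]],
                       protein_id = c("P2", "P1"))
  withp <- top_percent_table(res, 0.05, dp)
  expect_equal(withp$proteins_a[[1]], "P1,P2")
  expect_equal(withp$proteins_b[[1]], "")
})
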