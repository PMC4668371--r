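---
title: "Methods: MeSH-based disease similarity and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MeSH-based disease similarity and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshsim)
```

## The model

`meshsim` scores the similarity of two diseases from the MeSH terms that
describe them, using the structure of the MeSH hierarchy to weigh how much
a shared concept actually tells us.

**Ontology.** MeSH descriptors carry *tree numbers* — dot-separated codes
such as `A01.378.610` whose first letter names a category branch. Dropping
the last segment of a tree number yields the parent code, so the
descriptors of a branch form a rooted DAG in which a descriptor with
several tree numbers has several parents. Three modelling choices matter:

* a descriptor placed in several branches is a **single node** whose branch
  membership is an attribute. This is what makes separate branches
  connectable: shared descriptors create paths between them, and
  `merge_ontologies()` links any set of branches into one structure under a
  fresh synthetic root.
* the **synthetic root** is the parent of every top-level code and has
  information content 0. Every pair of terms therefore has at least one
  common ancestor and the Resnik score is total on the merged structure.
* a tree number whose parent code belongs to no selected descriptor is
  **retargeted** to the nearest selected ancestor code, and to the root if
  the chain runs out. This keeps a category subset connected. When branches
  are analysed separately, cross-branch edges are not represented at all;
  they exist only in the merged structure.

**Annotation.** A disease's annotation set is the union of the MeSH Main
Headings indexing the publications its entry references. Qualifiers
(`/drug therapy`) are stripped and the major-topic marker `*` is ignored,
so all headings weigh equally; heading strings are resolved to descriptor
ids by exact preferred-name match, and misses are reported rather than
guessed. Which catalogue entries count as diseases is the caller's
decision; the corpus type only tracks a universe of disease ids so that
coverage — the fraction of the universe with at least one usable term — is
always computable.

**Information content and similarity.** With `n(t)` the number of distinct
diseases annotated by term `t` or any descendant (True Path Rule,
propagated through *all* parents of multi-parent terms) and `N` the number
of annotated diseases, `IC(t) = -ln(n(t)/N)`. The Resnik similarity of two
terms is the IC of their most informative common ancestor; the similarity
of two diseases is the maximum over the cross product of their annotation
sets. The score is left unscaled: it is an unbounded non-negative real, and
any order-preserving rescaling would not change the rank-based evaluation
while inviting misreading (a `[0,1]` score is not a probability).

Comparison measures share the same infrastructure: Lin
(`2·resnik/(IC₁+IC₂)`), Jiang (`1 − d/M` with
`d = IC₁ + IC₂ − 2·resnik`), simUI and simGIC (Jaccard and IC-weighted
Jaccard of the ancestor-expanded sets), and four structure-blind baselines
(Jaccard, Dice, overlap coefficient, intersection size) on the raw sets.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| `categories` in the readers | `A, C, D, E, G` | branch letters | the anatomy, disease, chemical, technique and process branches combine high disease coverage with informative terms; fully configurable |
| logarithm base for IC | natural log | nats | any base is an order-preserving rescale; one is picked and documented |
| `threshold` in `build_seqsim_dataset()` | `1e-6` | e-value, **inclusive** | the standard cutoff for calling two protein sequences similar |
| `threshold_fraction` in `top_percent_table()` | `0.05` | fraction | the conventional "top 5%" shortlist; boundary ties are kept |
| `perplexity`, `pca_dims` in `embed_3d()` | 30, 50 | — | standard t-SNE defaults for corpus-scale maps; small fixtures need a smaller perplexity, and values at or above the point count are rejected |
| `top_k_classes` in `class_heatmap()` | 10 | classes | class analyses are most readable on the most populous classes |

## Numerical and degenerate-case choices

* **Lin 0/0.** If both terms have IC 0 the ratio is 0/0; the terms are
  fully uninformative and mutually indistinguishable, so the similarity is
  defined as 1. The same limit argument defines Jiang ≡ 1 when `M = 0`.
* **Jiang's `M`** is the maximum of the distance `d` over all term pairs
  with finite IC in the current (ontology, IC table) pair — a global
  constant, computed once and cached with the IC table and recorded in the
  similarity-file metadata. A per-pair-reachable variant was considered and
  rejected: it would make scores of different pairs incomparable.
* **Undefined is a value.** A disease pair with no usable terms on either
  side gets no score; it is excluded from AUC computation (both classes)
  and accounted for by the coverage component instead of being imputed.
  Terms annotated to diseases but absent from the ontology are silently
  excluded per pair.
* **AUC** is the Mann–Whitney rank statistic with average ranks for ties,
  which equals trapezoidal integration of the empirical ROC curve; the test
  suite checks the two routes against each other at 1e-12.
* **t-tests** (shared-gene and intra/inter-class comparisons) use Welch's
  unequal-variance form: the compared score distributions have visibly
  different spreads, and Welch is the safe default. Constant score vectors
  have no t statistic and yield `NA` rather than an error.
* **Quantiles** (top-percent table, percentile analyses) use the default
  type-7 interpolation of `stats::quantile()`, with ties at the boundary
  kept.
* **Similarity → distance** for the embedding is the linear transform
  `max_score − score`, with undefined pairs placed at `max_score`; a
  monotone alternative `1/(1+score)` is available. The distance input is
  pre-reduced by classical MDS to `pca_dims` dimensions before t-SNE
  (PCA on raw features is not meaningful for a precomputed distance); when
  `pca_dims` is at least the point count minus one the distances go to
  t-SNE directly.
* **Determinism.** Ancestor closures are memoised per ontology; all writers
  emit sorted rows, so rerunning any stage at a fixed seed is
  byte-identical.

## What the synthetic generator emulates — and what it does not

`random_ontology()` builds branch DAGs over a shared descriptor pool with a
controlled fraction of multi-branch descriptors (what links branches on
merging) and multi-parent nodes. All branches attach terms following one
global order, which guarantees the merged graph is acyclic by construction.

`planted_corpus()` emulates the statistical structure the evaluation
assumes:

* diseases fall into clusters; each cluster owns an anchor and a disjoint
  pool of **specific** terms, carved from the deepest descriptors so that
  shared within-cluster terms carry high IC. A disease's first draw is its
  cluster anchor with probability `within_cluster_term_overlap`, so at
  overlap 1 every within-cluster pair provably shares a term;
* every disease also draws from a small pool of **broad** terms (the
  shallowest descriptors). These become frequent and therefore
  uninformative, mimicking the ubiquitous broad headings of real MEDLINE
  indexing. They are what gives the structure-blind baselines false
  positives and saturates Lin/Jiang on unrelated pairs — without them the
  benchmark regime of real data cannot be reproduced;
* each disease carries one unique protein and gene plus a cluster gene;
  interactions wire same-cluster proteins, so the gold standard's positives
  are exactly the within-cluster pairs.

Features of real data the generator does **not** emulate: the heavy-tailed
size distribution of real annotation sets (tens to hundreds of headings);
citation-driven correlation between diseases studied in the same papers;
annotation errors and OMIM entry heterogeneity; and the scale (thousands of
diseases, millions of pairs). Passing tests on these fixtures therefore
demonstrate the correctness of the computations and the qualitative
behaviour of the measures, not quantitative performance on real corpora.

## Problem sizes used in the checks

The test suite runs entirely on generated fixtures: oracle-equivalence
checks use 50 random fixtures of 10–28 terms and 5–11 diseases, where every
measure is compared against naive reference implementations; the end-to-end
benchmark uses the package's default study conditions (60 terms in 3
branches, 24 diseases in 4 clusters, within-cluster overlap 0.8), and AUC
identities are checked on 210-pair score vectors. These sizes keep the
exhaustive references tractable while exercising every code path.

## Known limitations

* Only Main Heading descriptors are modelled — no supplementary concept
  records, qualifiers or term history.
* Heading resolution is exact-match on preferred names; entry-term
  thesaurus lookup is out of scope, so headings with renamed descriptors
  are dropped (and counted).
* The all-pairs scorer materialises a dense term-similarity matrix over
  terms with finite IC; this is the right trade-off up to a few thousand
  usable terms, beyond which a sparse ancestor-intersection strategy would
  be needed.
* Negatives in the evaluation are *all* eligible non-positive pairs;
  sampling is available for scale but changes the AUC estimator's
  variance.

## End-to-end example

```{r, eval = FALSE}
spec     <- fixture_spec(seed = 7)
branches <- random_ontology(spec)
fx       <- planted_corpus(spec, branches)
corpus   <- restrict_to_ontology(fx$corpus, fx$merged)
ict      <- compute_ic(fx$merged, corpus)

table9 <- compare_measures(
  corpus, fx$merged, ict,
  list(build_ppi_dataset(fx$disease_proteins, fx$interactions))
)
table9

res <- all_pairs(corpus, fx$merged, ict, "resnik")
autoplot(class_heatmap(res, fx$labels))
plot_embedding(embed_3d(similarity_to_distance(res), perplexity = 5),
               fx$labels)
```
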