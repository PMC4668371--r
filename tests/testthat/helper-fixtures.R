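# Hand-built and randomly generated fixtures shared across test files.

# Two branches (A, C) sharing one descriptor; depths up to 3.
#
#   C branch: C01 (Dis1) -> C01.100 (Shared), C01.200 (Dis2) -> C01.200.300 (Dis3)
#   A branch: A02 (Ana1) -> A02.200 (Shared)
toy_rows <- function() {
  tibble::tibble(
    term_id = c("T_DIS1", "T_SHARED", "T_DIS2", "T_DIS3", "T_ANA1", "T_SHARED"),
    name = c("Disease One", "Shared Term", "Disease Two", "Disease Three",
             "Anatomy One", "Shared Term"),
    tree_number = c("C01", "C01.100", "C01.200", "C01.200.300",
                    "A02", "A02.200")
  )
}

toy_ontology <- function(categories = c("A", "C")) {
  ontology_from_rows(toy_rows(), categories)
}

toy_corpus <- function() {
  annotation_corpus(list(
    d1 = c("T_DIS1", "T_SHARED"),
    d2 = c("T_DIS2", "T_DIS3"),
    d3 = c("T_ANA1"),
    d4 = c("T_DIS3", "T_SHARED")
  ), universe = c("d1", "d2", "d3", "d4", "d5"))
}

# A small random pipeline case; sizes stay inside the exhaustive oracle
# regime (<= 60 terms, <= 25 diseases).
rand_case <- function(seed, n_terms = 18, n_branches = 2, n_diseases = 8,
                      n_clusters = 2, overlap = 0.8,
                      branch_overlap_fraction = 0.3) {
  spec <- fixture_spec(
    n_terms = n_terms, n_branches = n_branches,
    branch_overlap_fraction = branch_overlap_fraction,
    n_diseases = n_diseases, n_clusters = n_clusters,
    terms_per_disease = c(2, 4), within_cluster_term_overlap = overlap,
    seed = seed
  )
  branches <- random_ontology(spec)
  fx <- planted_corpus(spec, branches)
  corpus <- suppressMessages(restrict_to_ontology(fx$corpus, fx$merged))
  list(spec = spec, branches = branches, merged = fx$merged, fx = fx,
       corpus = corpus, ict = compute_ic(fx$merged, corpus))
}

# Minimal MeSH descriptor XML with three descriptors: two in C, one in A;
# D03 sits in both C and A (two tree numbers).
toy_mesh_xml <- function(path) {
  writeLines(c(
    '<?xml version="1.0"?>',
    "<DescriptorRecordSet>",
    " <DescriptorRecord>",
    "  <DescriptorUI>D01</DescriptorUI>",
    "  <DescriptorName><String>Condition Alpha</String></DescriptorName>",
    "  <TreeNumberList><TreeNumber>C01</TreeNumber></TreeNumberList>",
    " </DescriptorRecord>",
    " <DescriptorRecord>",
    "  <DescriptorUI>D02</DescriptorUI>",
    "  <DescriptorName><String>Body Part Beta</String></DescriptorName>",
    "  <TreeNumberList><TreeNumber>A02</TreeNumber></TreeNumberList>",
    " </DescriptorRecord>",
    " <DescriptorRecord>",
    "  <DescriptorUI>D03</DescriptorUI>",
    "  <DescriptorName><String>Shared Gamma</String></DescriptorName>",
    "  <TreeNumberList>",
    "   <TreeNumber>C01.100</TreeNumber>",
    "   <TreeNumber>A02.200</TreeNumber>",
    "  </TreeNumberList>",
    " </DescriptorRecord>",
    "</DescriptorRecordSet>"
  ), path)
  path
}
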