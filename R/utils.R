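# Shared internal helpers: canonical unordered pairs and input coercion.

# Canonicalise two parallel id vectors so that a <= b lexicographically.
canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

pair_key <- function(a, b) {
  p <- canonical_pairs(a, b)
  paste(p$a, p$b, sep = "\r")
}

# All unordered pairs of distinct ids, lexicographically sorted, as a tibble.
all_unordered_pairs <- function(ids) {
  ids <- sort(unique(ids))
  n <- length(ids)
  if (n < 2L) {
    return(tibble::tibble(disease_a = character(), disease_b = character()))
  }
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  tibble::tibble(disease_a = ids[i], disease_b = ids[j])
}

# Coerce a two-column mapping (tibble or named list of character vectors)
# into a named list id -> sorted unique character vector.
as_id_sets <- function(x, key_col, value_col) {
  if (is.list(x) && !is.data.frame(x)) {
    if (length(x) == 0L) return(setNames(list(), character()))
    stopifnot(!is.null(names(x)))
    return(lapply(x, function(v) sort(unique(as.character(v)))))
  }
  stopifnot(is.data.frame(x), all(c(key_col, value_col) %in% names(x)))
  keys <- as.character(x[[key_col]])
  vals <- as.character(x[[value_col]])
  keep <- !is.na(vals) & vals != ""
  sets <- split(vals[keep], keys[keep])
  sets <- lapply(sets, function(v) sort(unique(v)))
  # keys that only ever appear with empty values still get an empty set
  empties <- setdiff(unique(keys), names(sets))
  if (length(empties)) {
    sets[empties] <- rep(list(character()), length(empties))
  }
  sets[order(names(sets))]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
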