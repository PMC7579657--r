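# Independent oracles kept deliberately naive: brute-force subset
# enumeration for frequent itemsets and a per-post pair counter for the
# co-occurrence network. They never share code with the implementation.

brute_force_frequent <- function(mat, min_support) {
  mat <- mat > 0
  items <- sort(colnames(mat))
  n <- nrow(mat)
  sets <- list()
  supports <- numeric(0)
  for (k in seq_along(items)) {
    combos <- utils::combn(items, k, simplify = FALSE)
    for (s in combos) {
      supp <- sum(apply(mat[, s, drop = FALSE], 1, all)) / n
      if (supp >= min_support) {
        sets[[length(sets) + 1L]] <- s
        supports <- c(supports, supp)
      }
    }
  }
  keys <- vapply(sets, paste, character(1), collapse = "\u001f")
  ord <- order(lengths(sets), keys)
  list(itemsets = sets[ord], support = supports[ord])
}

# compare an apriori result against the brute-force oracle
expect_matches_bruteforce <- function(fi, mat, min_support) {
  bf <- brute_force_frequent(mat, min_support)
  expect_equal(lapply(fi$itemset, identity), bf$itemsets)
  expect_equal(fi$support, bf$support, tolerance = 1e-12)
}

naive_pair_counts <- function(mat) {
  mat <- mat > 0
  items <- colnames(mat)
  w <- matrix(0L, length(items), length(items),
              dimnames = list(items, items))
  for (i in seq_len(nrow(mat))) {
    present <- items[mat[i, ]]
    if (length(present) < 2) next
    for (a in seq_len(length(present) - 1)) {
      for (b in seq((a + 1), length(present))) {
        w[present[a], present[b]] <- w[present[a], present[b]] + 1L
        w[present[b], present[a]] <- w[present[b], present[a]] + 1L
      }
    }
  }
  w
}
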