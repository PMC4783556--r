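# Shared fixtures, all built in code.

# Four records over two binary features; every pairwise quantity below has
# been worked out by hand in the tests that use it.
toy4 <- function() {
  categorical_dataset(data.frame(F1 = c("x", "x", "x", "y"),
                                 F2 = c("a", "a", "b", "b")))
}

# random categorical dataset for property-style tests
random_dataset <- function(n, s, max_categories = 4, seed = 1) {
  withr::with_seed(seed, {
    cells <- vapply(seq_len(s), function(l) {
      p <- sample(2:max_categories, 1)
      sample(letters[seq_len(p)], n, replace = TRUE)
    }, character(n))
    colnames(cells) <- paste0("F", seq_len(s))
    categorical_dataset(cells)
  })
}

# independent oracle: maximize p(w|x) + p(~w|y) - 1 over ALL subsets w of
# the co-feature's values, by enumeration
brute_force_pair_distance <- function(cpt, x, y) {
  vals <- colnames(cpt)
  best <- -Inf
  for (mask in 0:(2^length(vals) - 1)) {
    inw <- as.logical(bitwAnd(mask, 2^(seq_along(vals) - 1)))
    score <- sum(cpt[x, inw]) + sum(cpt[y, !inw]) - 1
    best <- max(best, score)
  }
  best
}

# write a small Wisconsin-dialect file (headerless, 11 columns) and return
# its path; rows are (id, f1..f9, class)
write_wbc_fixture <- function(rows, path = tempfile(fileext = ".data")) {
  writeLines(vapply(rows, paste, character(1), collapse = ","), path)
  path
}
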