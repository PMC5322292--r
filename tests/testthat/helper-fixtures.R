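# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

toy_counts <- function() {
  count_table(matrix(c(5, 3, 0,
                       0, 2, 4), nrow = 3,
                     dimnames = list(c("t1", "t2", "t3"), c("A", "B"))))
}

random_counts <- function(n_taxa, n_samples, seed, lambda = 4) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("s", seq_len(n_samples))))
  # guarantee non-empty samples and at least one positive count per taxon
  m[1, ] <- m[1, ] + 1
  m[, 1] <- m[, 1] + 1
  count_table(m)
}

balanced_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# association matrix with constant off-diagonal value
uniform_assoc <- function(ids, off, diag_val = 1) {
  n <- length(ids)
  m <- matrix(off, n, n, dimnames = list(ids, ids))
  diag(m) <- diag_val
  structure(m, source = "cooccurrence",
            class = c("association_matrix", "matrix", "array"))
}

random_assoc <- function(n, seed) {
  set.seed(seed)
  raw <- matrix(rnorm(n * n), n, n)
  raw <- (raw + t(raw)) / 2
  dimnames(raw) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  transform_association(raw)
}

expect_symmetric_01 <- function(m, tol = 1e-12) {
  expect_true(max(abs(m - t(m))) <= tol)
  expect_true(all(m >= -tol & m <= 1 + tol))
}
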