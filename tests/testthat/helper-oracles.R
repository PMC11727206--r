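# Plain-R oracles, independent of the compiled fast paths.

# Direct double-sum evaluation of the squared group-vs-group discrepancy.
disc2_by_sums <- function(g1, g0, kfun) {
  g1 <- as.matrix(g1); g0 <- as.matrix(g0)
  sum_pairs <- function(A, B) {
    s <- 0
    for (i in seq_len(nrow(A)))
      for (j in seq_len(nrow(B)))
        s <- s + kfun(A[i, ], B[j, ])
    s
  }
  n1 <- nrow(g1); n0 <- nrow(g0)
  sum_pairs(g1, g1) / n1^2 - 2 * sum_pairs(g1, g0) / (n1 * n0) +
    sum_pairs(g0, g0) / n0^2
}

energy_kfun <- function(x, y) -sqrt(sum((x - y)^2))

gauss_kfun <- function(x, y) exp(-sum((x - y)^2) / 2)

# all balanced treated sets of an n-unit instance (n even), each split once
balanced_splits <- function(n) {
  m <- n %/% 2
  sets <- utils::combn(n - 1, m - 1) + 1L
  lapply(seq_len(ncol(sets)), function(j) c(1L, sets[, j]))
}

rand_instance <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# a matrix whose rows come in exact duplicate pairs (optimum discrepancy 0)
duplicated_pairs <- function(m, p, seed) {
  set.seed(seed)
  Z <- matrix(rnorm(m * p), m, p)
  Z[rep(seq_len(m), each = 2), , drop = FALSE]
}
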