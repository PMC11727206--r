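# Kernels, generalized discrepancy, Mahalanobis imbalance.

test_that("named kernels evaluate their closed forms", {
  expect_equal(kernel_energy(c(0, 0), c(3, 4)), -5)
  expect_equal(kernel_energy(c(1), c(4)), -3)
  expect_equal(kernel_energy(c(1.3, -2, 7), c(1.3, -2, 7)), 0)
  expect_error(kernel_energy(c(1, 2), 1), "length")

  expect_equal(kernel_centered_l2(0.5, 0.5), 1)
  expect_equal(kernel_centered_l2(0, 0), 1.5)
  expect_equal(kernel_centered_l2(0, 1), 1.0)
  expect_error(kernel_centered_l2(-0.1, 0.5), "\\[0, 1\\]")

  # symmetry on random valid points
  set.seed(1)
  for (i in 1:20) {
    x <- runif(3); y <- runif(3)
    expect_equal(kernel_energy(x, y), kernel_energy(y, x))
    expect_equal(kernel_centered_l2(x, y), kernel_centered_l2(y, x))
  }
})

test_that("subset-to-full discrepancy matches direct double sums", {
  X <- matrix(c(0, 1), ncol = 1)
  expect_equal(discrepancy_to_full(X, X, energy_kernel()), 0)
  expect_equal(discrepancy_to_full(X[1, , drop = FALSE], X, energy_kernel()),
               sqrt(0.5))
  # brute-force double sums on a 4-point instance
  X4 <- matrix(0:3, ncol = 1)
  sub <- X4[c(1, 4), , drop = FALSE]
  manual <- sum(outer(0:3, 0:3, function(a, b) -abs(a - b))) / 16 -
    2 * sum(outer(0:3, c(0, 3), function(a, b) -abs(a - b))) / 8 +
    sum(outer(c(0, 3), c(0, 3), function(a, b) -abs(a - b))) / 4
  expect_equal(discrepancy_to_full(sub, X4, energy_kernel()), sqrt(manual))
  expect_error(discrepancy_to_full(rbind(X4, 0), X4, energy_kernel()), "more rows")
})

test_that("group discrepancy matches the three-term expansion and the R oracle", {
  expect_equal(discrepancy_between_groups(matrix(0), matrix(1), energy_kernel()),
               sqrt(2))
  expect_equal(discrepancy_between_groups(matrix(c(0, 1)), matrix(c(2, 3)),
                                          energy_kernel()), sqrt(3))
  g <- matrix(c(0.2, 0.8, 0.5), ncol = 1)
  expect_equal(discrepancy_between_groups(g, g, energy_kernel()), 0)
  expect_equal(discrepancy_between_groups(g, g, centered_l2_kernel()), 0)

  set.seed(42)
  for (rep in 1:10) {
    g1 <- matrix(rnorm(6), ncol = 2)
    g0 <- matrix(rnorm(8), ncol = 2)
    expect_equal(discrepancy_between_groups(g1, g0, energy_kernel())^2,
                 disc2_by_sums(g1, g0, energy_kfun), tolerance = 1e-10)
    # symmetry in the two groups
    expect_equal(discrepancy_between_groups(g1, g0, energy_kernel()),
                 discrepancy_between_groups(g0, g1, energy_kernel()))
    # row permutations within groups are irrelevant
    expect_equal(
      discrepancy_between_groups(g1[sample(3), , drop = FALSE],
                                 g0[sample(4), , drop = FALSE],
                                 energy_kernel()),
      discrepancy_between_groups(g1, g0, energy_kernel())
    )
  }
})

test_that("user kernels go through the same machinery", {
  gk <- user_kernel(gauss_kfun, name = "gaussian")
  set.seed(7)
  g1 <- matrix(rnorm(8), ncol = 2)
  g0 <- matrix(rnorm(6), ncol = 2)
  expect_equal(discrepancy_between_groups(g1, g0, gk)^2,
               disc2_by_sums(g1, g0, gauss_kfun), tolerance = 1e-10)
})

test_that("splitting identity: D(X1,X) + D(X0,X) = D(X1,X0) for balanced splits", {
  kernels <- list(energy = energy_kernel(), gauss = user_kernel(gauss_kfun))
  for (rep in 1:100) {
    set.seed(rep)
    n <- 2 * sample(2:8, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    tr <- sample(n, n / 2)
    for (kern in kernels) {
      d1 <- discrepancy_to_full(X[tr, , drop = FALSE], X, kern)
      d0 <- discrepancy_to_full(X[-tr, , drop = FALSE], X, kern)
      dg <- discrepancy_between_groups(X[tr, , drop = FALSE],
                                       X[-tr, , drop = FALSE], kern)
      expect_equal(d1 + d0, dg, tolerance = 1e-8)
    }
  }
  # unit-cube data for the centered L2 kernel
  for (rep in 1:20) {
    set.seed(rep + 500)
    X <- matrix(runif(24), 12, 2)
    tr <- sample(12, 6)
    d1 <- discrepancy_to_full(X[tr, , drop = FALSE], X, centered_l2_kernel())
    d0 <- discrepancy_to_full(X[-tr, , drop = FALSE], X, centered_l2_kernel())
    dg <- discrepancy_between_groups(X[tr, , drop = FALSE],
                                     X[-tr, , drop = FALSE],
                                     centered_l2_kernel())
    expect_equal(d1 + d0, dg, tolerance = 1e-8)
  }
})

test_that("energy discrepancy is nonnegative on random instances", {
  for (rep in 1:50) {
    set.seed(rep)
    g1 <- matrix(rnorm(10), ncol = 2)
    g0 <- matrix(rnorm(12), ncol = 2)
    expect_gte(discrepancy_between_groups(g1, g0, energy_kernel()), 0)
  }
})

test_that("Mahalanobis imbalance: hand value, affine invariance, chi-square null", {
  X <- matrix(c(0, 0, 2, 2), ncol = 1)
  expect_equal(mahalanobis_distance(X, c(0, 0, 1, 1)), 3)
  # zero mean difference
  Xz <- matrix(c(1, 2, 1, 2), ncol = 1)
  expect_equal(mahalanobis_distance(Xz, c(1, 0, 0, 1)), 0)

  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  tr <- integer(20); tr[sample(20, 10)] <- 1L
  m0 <- mahalanobis_distance(X, tr)
  for (rep in 1:5) {
    A <- matrix(rnorm(9), 3, 3) + diag(3)
    b <- rnorm(3)
    Xa <- sweep(X %*% A, 2, b, "+")
    expect_equal(mahalanobis_distance(Xa, tr), m0, tolerance = 1e-6)
  }
  # agrees with the stats::mahalanobis quadratic form
  d <- colMeans(X[tr == 1, ]) - colMeans(X[tr == 0, ])
  oracle <- (10 * 10 / 20) *
    stats::mahalanobis(d, center = rep(0, 3), cov = cov(X))
  expect_equal(m0, oracle)
})

test_that("singular covariance falls back to a pseudo-inverse with a warning", {
  X <- cbind(1:6, 2 * (1:6))  # rank 1
  tr <- c(1, 1, 1, 0, 0, 0)
  expect_warning(v <- mahalanobis_distance(X, tr), "pseudo-inverse")
  expect_gte(v, 0)
})

test_that("degenerate inputs error informatively", {
  expect_error(discrepancy_between_groups(matrix(numeric(0), 0, 1), matrix(1),
                                          energy_kernel()), "nonempty")
  expect_error(mahalanobis_distance(matrix(rnorm(10), 5), c(1, 1, 1, 1, 1)),
               "nonempty")
  expect_error(assignment_discrepancy(matrix(rnorm(10), 5), c(1, 0, 1),
                                      energy_kernel()), "length")
  expect_error(discrepancy_between_groups(matrix(NA_real_), matrix(1),
                                          energy_kernel()), "finite|missing")
})
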