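# Balanced-partition optimizers against the exhaustive oracle.

test_that("brute force finds the exact minimum with lexicographic ties", {
  X4 <- matrix(0:3, ncol = 1)
  bf <- brute_force_partition(X4, energy_kernel())
  expect_equal(bf$discrepancy, 1)
  expect_equal(bf$treated_indices, c(1L, 3L))  # ties with {1,4} resolved
  # n = 2: the only split
  X2 <- matrix(c(-1, 2), ncol = 1)
  bf2 <- brute_force_partition(X2, energy_kernel())
  expect_equal(bf2$discrepancy, sqrt(-2 * kernel_energy(-1, 2)))
  # duplicated pairs admit a perfect split
  Xd <- duplicated_pairs(4, 2, seed = 9)
  expect_lt(brute_force_partition(Xd, energy_kernel())$discrepancy, 1e-8)
  expect_error(brute_force_partition(matrix(rnorm(40), 20), energy_kernel()),
               "n <= 16")
})

test_that("exchange heuristic: optimality on small instances, monotonicity, determinism", {
  X4 <- matrix(0:3, ncol = 1)
  expect_equal(exchange_optimize(X4, energy_kernel(), seed = 2)$discrepancy, 1)

  Xd <- duplicated_pairs(5, 2, seed = 1)
  expect_lt(exchange_optimize(Xd, energy_kernel(), seed = 1)$discrepancy, 1e-8)

  hits <- 0
  for (s in 1:20) {
    X <- rand_instance(n = 8 + 2 * (s %% 2), p = 1, seed = s)
    opt <- brute_force_partition(X, energy_kernel())$discrepancy
    got <- exchange_optimize(X, energy_kernel(), seed = s)$discrepancy
    expect_gte(got, opt - 1e-10)  # oracle lower-bounds every heuristic
    if (got <= opt + 1e-8) hits <- hits + 1
    # final discrepancy never exceeds the starting partition's
    init <- seq_len(nrow(X) / 2)
    started <- exchange_optimize(X, energy_kernel(), init = init)
    d_init <- assignment_discrepancy(
      X, replace(integer(nrow(X)), init, 1L), energy_kernel())
    expect_lte(started$discrepancy, d_init + 1e-12)
  }
  expect_gte(hits / 20, 0.8)

  # identical seed, identical result; and the result recomputes exactly
  X <- rand_instance(30, 3, seed = 99)
  a <- exchange_optimize(X, energy_kernel(), seed = 5)
  b <- exchange_optimize(X, energy_kernel(), seed = 5)
  expect_identical(a$treated_indices, b$treated_indices)
  expect_equal(a$discrepancy,
               discrepancy_between_groups(X[a$treated_indices, ],
                                          X[a$control_indices, ],
                                          energy_kernel()),
               tolerance = 1e-9)
  expect_error(exchange_optimize(matrix(rnorm(3), 3), energy_kernel()), "n >= 4")
})

test_that("twin split handles the energy kernel and beats random partitions", {
  X4 <- matrix(0:3, ncol = 1)
  expect_equal(twin_split(X4, seed = 3)$discrepancy, 1)
  expect_lt(twin_split(duplicated_pairs(6, 2, seed = 2), seed = 1)$discrepancy,
            1e-8)
  expect_error(twin_split(X4, centered_l2_kernel()), "energy")

  # large instance: below the 1st percentile of random balanced partitions
  X <- gen_covariates(1000, 5, "uniform", seed = 10)
  tw <- twin_split(X, seed = 1)
  set.seed(11)
  ref <- replicate(500, {
    tr <- sample(1000, 500)
    discrepancy_between_groups(X[tr, ], X[-tr, ], energy_kernel())
  })
  expect_lt(tw$discrepancy, quantile(ref, 0.01))
})

test_that("CDF-transform split works on the unit-cube scale", {
  X <- matrix(c(10, 20, 30, 40), ncol = 1)
  expect_equal(as.vector(cdf_transform(X)), c(0.25, 0.5, 0.75, 1))
  expect_warning(cdf_transform(cbind(1:4, rep(2, 4))), "constant")

  X <- rand_instance(60, 3, seed = 21)
  dd <- dds_split(X, seed = 4)
  U <- dd$transformed
  expect_true(all(U > 0 & U <= 1))
  # reported discrepancy is measured on the transformed coordinates
  expect_equal(dd$discrepancy,
               discrepancy_between_groups(U[dd$treated_indices, ],
                                          U[dd$control_indices, ],
                                          centered_l2_kernel()),
               tolerance = 1e-9)
  # beats the best of 500 random partitions on the same transform
  set.seed(22)
  ref <- replicate(500, {
    tr <- sample(60, 30)
    discrepancy_between_groups(U[tr, ], U[-tr, ], centered_l2_kernel())
  })
  expect_lte(dd$discrepancy, min(ref) + 1e-12)
})

test_that("Monte Carlo search is a running minimum with stable ties", {
  X <- rand_instance(12, 2, seed = 31)
  one <- mc_search(X, energy_kernel(), M = 1, seed = 8)
  expect_equal(length(one$draws), 1L)
  expect_equal(one$discrepancy, one$draws[1])
  prev <- Inf
  for (M in c(5, 20, 80)) {
    got <- mc_search(X, energy_kernel(), M = M, seed = 8)$discrepancy
    expect_lte(got, prev + 1e-12)  # nested draws under one seed
    prev <- got
  }
  expect_gte(prev, brute_force_partition(X, energy_kernel())$discrepancy - 1e-10)
})

test_that("optimized partitions decay faster than n^(-1/2), random ones do not", {
  ns <- c(64, 128, 256, 512)
  med_opt <- med_rand <- numeric(length(ns))
  for (i in seq_along(ns)) {
    n <- ns[i]
    opt <- rand <- numeric(5)
    for (s in 1:5) {
      set.seed(1000 * i + s)
      X <- matrix(runif(2 * n), n, 2)
      opt[s] <- sqrt(n) * twin_split(X, seed = s)$discrepancy
      tr <- sample(n, n / 2)
      rand[s] <- sqrt(n) *
        discrepancy_between_groups(X[tr, ], X[-tr, ], energy_kernel())
    }
    med_opt[i] <- median(opt)
    med_rand[i] <- median(rand)
  }
  expect_true(all(diff(med_opt) < 0))              # sqrt(n) * D_K shrinks
  expect_lt(abs(med_rand[4] - med_rand[1]), 0.5 * med_rand[1])  # roughly flat
})

test_that("partition results are well formed and serializable", {
  X <- rand_instance(10, 2, seed = 77)
  pr <- exchange_optimize(X, energy_kernel(), seed = 1)
  expect_s3_class(pr, "partition_result")
  expect_setequal(c(pr$treated_indices, pr$control_indices), 1:10)
  expect_equal(length(pr$treated_indices), 5L)
  tmp <- tempfile(fileext = ".csv")
  write_partition(pr, tmp)
  expect_equal(read_assignment(tmp), partition_to_assignment(pr))
  meta <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(meta$n1, 5L)
  unlink(c(tmp, paste0(tmp, ".json")))
})
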