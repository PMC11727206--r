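# Generalized discrepancy (maximum mean discrepancy) and Mahalanobis imbalance.

# Square root with the clamping rule for quadratic forms: kernel double sums
# can land a hair below zero in floating point; anything worse than -1e-10 is
# a real error (e.g. an indefinite user kernel).
sqrt_clamped <- function(d2) {
  if (d2 < 0) {
    if (d2 < -1e-10) {
      stop(sprintf("squared discrepancy is negative (%.3e); kernel may not be positive semi-definite on this data", d2),
           call. = FALSE)
    }
    d2 <- 0
  }
  sqrt(d2)
}

#' Generalized discrepancy between a subset and the full covariate set
#'
#' Computes \eqn{D_K(X_t, X)}, the kernel (RKHS) distance between the
#' empirical distribution of a subset of units and that of the full set:
#' \deqn{D_K(X_t, X)^2 = n^{-2}\sum_{x,y \in X} K(x,y)
#'   - 2 (n n_t)^{-1} \sum_{x \in X, y \in X_t} K(x,y)
#'   + n_t^{-2} \sum_{x,y \in X_t} K(x,y).}
#' The double sums run over all ordered pairs including the diagonal. Tiny
#' negative values of the quadratic form (above \eqn{-10^{-10}}) are clamped
#' to zero before the square root.
#'
#' @param subset Covariate matrix of the subset (rows taken from `full`).
#' @param full Covariate matrix of all n units.
#' @param kernel A [kernel_spec][energy_kernel] object.
#' @return The nonnegative discrepancy \eqn{D_K(X_t, X)}.
#' @seealso [discrepancy_between_groups()] for the group-vs-group form.
#' @examples
#' X <- matrix(c(0, 1), ncol = 1)
#' discrepancy_to_full(X[1, , drop = FALSE], X, energy_kernel())  # sqrt(0.5)
#' @export
discrepancy_to_full <- function(subset, full, kernel) {
  subset <- as_one_group(subset, "subset")
  full <- as_covariate_matrix(full, "full")
  if (nrow(subset) >= nrow(full)) {
    # subset == full is allowed and gives exactly 0 by cancellation
    if (nrow(subset) > nrow(full)) {
      stop("`subset` cannot have more rows than `full`", call. = FALSE)
    }
  }
  n <- nrow(full); nt <- nrow(subset)
  s_full <- sum(kernel_gram(kernel, full))
  s_sub <- sum(kernel_gram_any(kernel, subset))
  s_cross <- sum(kernel_cross_gram(kernel, full, subset))
  d2 <- s_full / n^2 - 2 * s_cross / (n * nt) + s_sub / nt^2
  sqrt_clamped(d2)
}

#' Generalized discrepancy between treatment and control covariates
#'
#' Computes \eqn{D_K(X_1, X_0)}, the kernel distance between the empirical
#' covariate distributions of two groups, via the three-term expansion
#' \deqn{n_1^{-2}\sum\sum K(X_1, X_1) - 2(n_1 n_0)^{-1}\sum\sum K(X_1, X_0)
#'  + n_0^{-2}\sum\sum K(X_0, X_0),}
#' square-rooted with the same clamping rule as [discrepancy_to_full()].
#' This is a maximum mean discrepancy; with the energy kernel it is the
#' energy distance between the two point sets, zero exactly when the two
#' empirical distributions coincide.
#'
#' @param g1,g0 Covariate matrices of the two groups (both nonempty).
#' @param kernel A [kernel_spec][energy_kernel] object.
#' @return The nonnegative discrepancy \eqn{D_K(X_1, X_0)}.
#' @examples
#' discrepancy_between_groups(matrix(0), matrix(1), energy_kernel())  # sqrt(2)
#' @export
discrepancy_between_groups <- function(g1, g0, kernel) {
  g1 <- as_one_group(g1, "g1"); g0 <- as_one_group(g0, "g0")
  if (ncol(g1) != ncol(g0)) stop("covariate dimensions differ", call. = FALSE)
  n1 <- nrow(g1); n0 <- nrow(g0)
  s11 <- sum(kernel_gram_any(kernel, g1))
  s00 <- sum(kernel_gram_any(kernel, g0))
  s10 <- sum(kernel_cross_gram(kernel, g1, g0))
  d2 <- s11 / n1^2 - 2 * s10 / (n1 * n0) + s00 / n0^2
  sqrt_clamped(d2)
}

# group matrices may legitimately have a single row
as_one_group <- function(g, arg) {
  if (is.data.frame(g)) g <- as.matrix(g)
  if (is.vector(g) && is.numeric(g)) g <- matrix(g, ncol = 1L)
  if (!is.matrix(g) || !is.numeric(g) || nrow(g) < 1L) {
    stop(sprintf("`%s` must be a nonempty numeric covariate matrix", arg),
         call. = FALSE)
  }
  if (anyNA(g) || any(!is.finite(g))) {
    stop(sprintf("`%s` contains missing or non-finite entries", arg), call. = FALSE)
  }
  storage.mode(g) <- "double"
  g
}

kernel_gram_any <- function(kernel, X) {
  if (nrow(X) == 1L) {
    matrix(kernel$eval(X[1, ], X[1, ]), 1L, 1L)
  } else {
    kernel_gram(kernel, X)
  }
}

#' Assignment-level discrepancy
#'
#' Convenience wrapper: splits the rows of `X` by a 0/1 treatment vector and
#' returns \eqn{D_K(X_1, X_0)}.
#'
#' @param X Covariate matrix (n x p).
#' @param treatment 0/1 vector of length n.
#' @param kernel A [kernel_spec][energy_kernel] object.
#' @return The nonnegative discrepancy between the two groups.
#' @export
assignment_discrepancy <- function(X, treatment, kernel) {
  X <- as_covariate_matrix(X)
  treatment <- check_assignment(treatment, nrow(X))
  discrepancy_between_groups(X[treatment == 1L, , drop = FALSE],
                             X[treatment == 0L, , drop = FALSE], kernel)
}

#' Mahalanobis distance between treatment-group covariate means
#'
#' The classical re-randomization imbalance statistic
#' \deqn{M(X_1, X_0) = \frac{n_1 n_0}{n} (\bar X_1 - \bar X_0)^\top
#'   \mathrm{cov}(X)^{-1} (\bar X_1 - \bar X_0),}
#' where \eqn{\bar X_t} is the covariate mean of group t and
#' \eqn{\mathrm{cov}(X)} the sample covariance of all n units (denominator
#' n-1). Under complete randomization with moderately large groups, M is
#' asymptotically \eqn{\chi^2_p}. A singular covariance triggers a warning
#' and a Moore-Penrose pseudo-inverse.
#'
#' @param X Covariate matrix (n x p).
#' @param treatment 0/1 vector of length n.
#' @return The nonnegative Mahalanobis imbalance.
#' @examples
#' X <- matrix(c(0, 0, 2, 2), ncol = 1)
#' mahalanobis_distance(X, c(0, 0, 1, 1))  # 3
#' @export
mahalanobis_distance <- function(X, treatment) {
  X <- as_covariate_matrix(X)
  treatment <- check_assignment(treatment, nrow(X))
  n <- nrow(X); p <- ncol(X)
  n1 <- sum(treatment); n0 <- n - n1
  if (n < p + 1L) {
    warning("n < p + 1: sample covariance is rank deficient", call. = FALSE)
  }
  d <- colMeans(X[treatment == 1L, , drop = FALSE]) -
    colMeans(X[treatment == 0L, , drop = FALSE])
  S <- cov(X)
  Sinv <- tryCatch(solve(S), error = function(e) {
    warning("singular covariate covariance; using pseudo-inverse", call. = FALSE)
    MASS::ginv(S)
  })
  val <- (n1 * n0 / n) * drop(t(d) %*% Sinv %*% d)
  max(val, 0)
}
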