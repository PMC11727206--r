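# Treatment-assignment generators: CRE, ReM, MODE, and relaxed
# discrepancy-based re-randomization.

#' Completely randomized assignment (CRE)
#'
#' Draws uniformly from the set of assignments with exactly `n1` treated
#' units.
#'
#' @param n Number of units.
#' @param n1 Number treated (1 <= n1 <= n - 1); defaults to a balanced
#'   design.
#' @param seed Integer seed.
#' @return Integer 0/1 vector of length n with `sum == n1`.
#' @export
cre_assign <- function(n, n1 = ceiling(n / 2), seed = 1L) {
  n <- as.integer(n); n1 <- as.integer(n1)
  if (n < 2L) stop("need at least 2 units", call. = FALSE)
  if (n1 < 1L || n1 > n - 1L) {
    stop("`n1` must satisfy 1 <= n1 <= n - 1", call. = FALSE)
  }
  treatment <- integer(n)
  treatment[with_seed(seed, sample.int(n, n1))] <- 1L
  treatment
}

#' Re-randomization acceptance threshold for the Mahalanobis criterion
#'
#' Returns the q-quantile of the chi-square distribution with p degrees of
#' freedom, the conventional threshold `a` for re-randomization with
#' acceptance probability approximately q: the Mahalanobis imbalance of a
#' balanced completely randomized assignment is asymptotically
#' \eqn{\chi^2_p}, so assignments with \eqn{M(X_1, X_0) \le a} are accepted
#' a fraction q of the time.
#'
#' @param p Covariate dimension.
#' @param q Target acceptance probability in (0, 1); default 0.2.
#' @return The threshold `a`.
#' @examples
#' rem_threshold(2, 0.2)  # -2 * log(0.8)
#' @export
rem_threshold <- function(p, q = 0.2) {
  p <- as.integer(p)
  if (p < 1L) stop("`p` must be at least 1", call. = FALSE)
  if (!is.numeric(q) || q <= 0 || q >= 1) {
    stop("`q` must lie strictly between 0 and 1", call. = FALSE)
  }
  qchisq(q, df = p)
}

#' Re-randomized assignment with the Mahalanobis criterion (ReM)
#'
#' Repeatedly draws balanced completely randomized assignments until the
#' Mahalanobis imbalance satisfies \eqn{M(X_1, X_0) \le a}.
#'
#' @param X Covariate matrix (n x p).
#' @param a Acceptance threshold (see [rem_threshold()]).
#' @param seed Integer seed.
#' @param max_draws Give up (with the empirical acceptance diagnostic) after
#'   this many rejected draws.
#' @return Integer 0/1 vector; attribute `draws` records how many candidate
#'   assignments were drawn.
#' @export
rem_assign <- function(X, a, seed = 1L, max_draws = 1e5) {
  X <- as_covariate_matrix(X)
  if (!is.numeric(a) || a <= 0) stop("`a` must be positive", call. = FALSE)
  n <- nrow(X)
  m1 <- as.integer(floor(n / 2))
  with_seed(seed, {
    for (draw in seq_len(max_draws)) {
      treatment <- integer(n)
      treatment[sample.int(n, m1)] <- 1L
      if (mahalanobis_distance(X, treatment) <= a) {
        attr(treatment, "draws") <- draw
        return(treatment)
      }
    }
    stop(sprintf("rem_assign(): no acceptable assignment in %d draws (empirical acceptance rate < %.2g); raise `a` or `max_draws`",
                 as.integer(max_draws), 1 / max_draws), call. = FALSE)
  })
}

#' Minimax optimal deterministic experiment (MODE) assignment
#'
#' Builds the (asymptotic) MODE: the balanced partition minimizing the
#' generalized discrepancy \eqn{D_K(X_1, X_0)}, with the optimizer chosen by
#' the kernel, and treatment given to the optimized half \eqn{X_1^*}:
#'
#' * energy kernel: the twinning branch ([twin_split()]);
#' * centered L2 kernel: the marginal-CDF-transform branch ([dds_split()]);
#' * any other (user) kernel: Monte Carlo search over `M` random balanced
#'   partitions ([mc_search()]).
#'
#' Either labeling of the two optimized halves is a MODE; the treated half
#' reported here is \eqn{X_1^*}, and flipping the labels leaves the
#' discrepancy unchanged.
#'
#' @param X Covariate matrix (n x p, n >= 4).
#' @param kernel A [kernel_spec][energy_kernel] object.
#' @param M Monte Carlo budget for the fallback branch.
#' @param seed Integer seed.
#' @return Integer 0/1 vector with \eqn{n_1 = \lceil n/2 \rceil} ones;
#'   attributes `discrepancy` and `method` carry the optimizer result.
#' @export
mode_assign <- function(X, kernel = energy_kernel(), M = 500L, seed = 1L) {
  X <- as_covariate_matrix(X)
  if (nrow(X) < 4L) stop("mode_assign() needs n >= 4", call. = FALSE)
  part <- switch(kernel$kind,
    energy = twin_split(X, kernel, seed = seed),
    centered_l2 = dds_split(X, kernel, seed = seed),
    mc_search(X, kernel, M = M, seed = seed)
  )
  treatment <- partition_to_assignment(part)
  attr(treatment, "discrepancy") <- part$discrepancy
  attr(treatment, "method") <- part$method
  treatment
}

#' Relaxed re-randomization on the generalized discrepancy
#'
#' A randomized compromise between the MODE and complete randomization:
#' the acceptance region is \eqn{D_K(X_1, X_0) \le \hat q_{D_K,\alpha}},
#' where \eqn{\hat q_{D_K,\alpha}} is the empirical \eqn{\alpha}-quantile of
#' the discrepancy over `n_quantile_draws` random balanced partitions.
#' As \eqn{\alpha \to 1} this degenerates to the CRE; small \eqn{\alpha}
#' concentrates the randomization near the minimum-discrepancy partitions.
#'
#' @param X Covariate matrix (n x p).
#' @param kernel A [kernel_spec][energy_kernel] object.
#' @param alpha Acceptance level in (0, 1].
#' @param n_quantile_draws Monte Carlo budget for estimating the quantile.
#' @param seed Integer seed.
#' @param max_draws Rejection-sampling cap.
#' @return Integer 0/1 vector; attributes `threshold` (the estimated
#'   quantile), `discrepancy` (of the accepted draw) and `draws`.
#' @export
relaxed_rerandomize <- function(X, kernel = energy_kernel(), alpha = 0.1,
                                n_quantile_draws = 1000L, seed = 1L,
                                max_draws = 1e5) {
  X <- as_covariate_matrix(X)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(X)
  m1 <- as.integer(floor(n / 2))
  G <- kernel_gram(kernel, X)
  with_seed(seed, {
    dvals <- replicate(n_quantile_draws, {
      tr <- sample.int(n, m1)
      sqrt(max(disc2_from_gram_cpp(G, tr - 1L, setdiff(seq_len(n), tr) - 1L), 0))
    })
    qhat <- unname(quantile(dvals, probs = alpha, type = 1))
    for (draw in seq_len(max_draws)) {
      tr <- sample.int(n, m1)
      d <- sqrt(max(disc2_from_gram_cpp(G, tr - 1L, setdiff(seq_len(n), tr) - 1L), 0))
      if (d <= qhat) {
        treatment <- integer(n)
        treatment[tr] <- 1L
        attr(treatment, "threshold") <- qhat
        attr(treatment, "discrepancy") <- d
        attr(treatment, "draws") <- draw
        return(treatment)
      }
    }
    stop(sprintf("relaxed_rerandomize(): no acceptable assignment in %d draws",
                 as.integer(max_draws)), call. = FALSE)
  })
}
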