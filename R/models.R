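# Synthetic covariates and potential-outcome models for the replication
# engine.

#' Generate synthetic covariates
#'
#' Draws an n x p matrix of iid covariates from one of the two study laws:
#' `"uniform"` is U\[-3, 3\] and `"normal"` is N(0, 3) read as variance 3,
#' so both laws share mean 0 and variance 3 per coordinate and are
#' moment-comparable.
#'
#' @param n Number of units (>= 2).
#' @param p Number of covariates (>= 1).
#' @param law `"uniform"` or `"normal"`.
#' @param seed Integer seed.
#' @return An n x p numeric matrix.
#' @export
gen_covariates <- function(n, p, law = c("uniform", "normal"), seed = 1L) {
  law <- match.arg(law)
  n <- as.integer(n); p <- as.integer(p)
  if (n < 2L || p < 1L) stop("need n >= 2 and p >= 1", call. = FALSE)
  with_seed(seed, {
    vals <- switch(law,
      uniform = runif(n * p, -3, 3),
      normal = rnorm(n * p, 0, sqrt(3))
    )
    matrix(vals, nrow = n, ncol = p)
  })
}

xtilde <- function(X) rowMeans(X)

#' Benchmark potential-outcome models
#'
#' The four benchmark specifications of the mean and variance functions,
#' all driven by the covariate average \eqn{\tilde x = \sum_j x_j / p}:
#'
#' * C1: \eqn{f_1 = e^{\tilde x}}, \eqn{f_0 = 1 + \tilde x}, no noise;
#' * C2: the C1 means with unit-variance Gaussian noise in both arms;
#' * C3: \eqn{f_1 = e^{\tilde x} + e^{\tilde x / 2}},
#'   \eqn{f_0 = e^{\tilde x} - e^{\tilde x / 2}}, no noise;
#' * C4: the C3 means with unit-variance Gaussian noise in both arms.
#'
#' C1 and C3 have fixed (deterministic) potential outcomes; C2 and C4 add
#' independent N(0, 1) noise to each arm.
#'
#' @param id One of `"C1"`, `"C2"`, `"C3"`, `"C4"`.
#' @return An object of class `outcome_model`: functions `f1`, `f0`
#'   (conditional means) and `s1sq`, `s0sq` (conditional variances), each
#'   mapping an n x p covariate matrix to an n-vector.
#' @seealso [custom_outcome_model()] to supply arbitrary functions.
#' @export
outcome_model <- function(id = c("C1", "C2", "C3", "C4")) {
  id <- match.arg(id)
  noisy <- id %in% c("C2", "C4")
  s2 <- if (noisy) {
    function(X) rep(1, nrow(X))
  } else {
    function(X) rep(0, nrow(X))
  }
  if (id %in% c("C1", "C2")) {
    f1 <- function(X) exp(xtilde(X))
    f0 <- function(X) 1 + xtilde(X)
  } else {
    f1 <- function(X) exp(xtilde(X)) + exp(xtilde(X) / 2)
    f0 <- function(X) exp(xtilde(X)) - exp(xtilde(X) / 2)
  }
  structure(list(id = id, f1 = f1, f0 = f0, s1sq = s2, s0sq = s2,
                 noise = "gaussian"),
            class = "outcome_model")
}

#' @rdname outcome_model
#' @param f1,f0 Mean functions (n x p matrix -> n-vector).
#' @param s1sq,s0sq Variance functions (n x p matrix -> nonnegative
#'   n-vector); default zero.
#' @param id Label.
#' @export
custom_outcome_model <- function(f1, f0,
                                 s1sq = function(X) rep(0, nrow(X)),
                                 s0sq = function(X) rep(0, nrow(X)),
                                 id = "custom") {
  stopifnot(is.function(f1), is.function(f0), is.function(s1sq),
            is.function(s0sq))
  structure(list(id = id, f1 = f1, f0 = f0, s1sq = s1sq, s0sq = s0sq,
                 noise = "gaussian"),
            class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("<outcome_model %s>\n", x$id))
  invisible(x)
}

#' Evaluate an outcome model at covariate points
#'
#' @param model An [outcome_model()].
#' @param X Covariate matrix (or a single p-vector).
#' @return Data frame with columns `f1`, `f0`, `s1sq`, `s0sq`, one row per
#'   unit.
#' @export
eval_model <- function(model, X) {
  stopifnot(inherits(model, "outcome_model"))
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, nrow = 1L)
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  out <- data.frame(f1 = model$f1(X), f0 = model$f0(X),
                    s1sq = model$s1sq(X), s0sq = model$s0sq(X))
  if (any(!is.finite(as.matrix(out)))) {
    stop("outcome model returned non-finite values", call. = FALSE)
  }
  if (any(out$s1sq < 0) || any(out$s0sq < 0)) {
    stop("variance functions must be nonnegative", call. = FALSE)
  }
  out
}

#' Generate potential and observed outcomes
#'
#' Draws \eqn{Y_i(1) = f_1(X_i) + \sigma_1(X_i) u_i} and
#' \eqn{Y_i(0) = f_0(X_i) + \sigma_0(X_i) v_i} with independent standard
#' Gaussian `u`, `v`, and composes the observed outcome
#' \eqn{Y_i = T_i Y_i(1) + (1 - T_i) Y_i(0)}.
#'
#' @param X Covariate matrix.
#' @param model An [outcome_model()].
#' @param treatment 0/1 vector of length n.
#' @param seed Integer seed for the noise draws.
#' @return List with vectors `y1`, `y0`, and `observed`.
#' @export
gen_outcomes <- function(X, model, treatment, seed = 1L) {
  X <- as_covariate_matrix(X)
  treatment <- check_assignment(treatment, nrow(X))
  vals <- eval_model(model, X)
  n <- nrow(X)
  uv <- with_seed(seed, list(u = rnorm(n), v = rnorm(n)))
  y1 <- vals$f1 + sqrt(vals$s1sq) * uv$u
  y0 <- vals$f0 + sqrt(vals$s0sq) * uv$v
  list(y1 = y1, y0 = y0,
       observed = ifelse(treatment == 1L, y1, y0))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' \eqn{\sup_y |\hat F_a(y) - \hat F_b(y)|} over the pooled sample points,
#' where \eqn{\hat F_a}, \eqn{\hat F_b} are the empirical CDFs of the two
#' samples. Used to compare the distribution of all units' treated-arm
#' potential outcomes with the observed outcomes of the treated group.
#'
#' @param a,b Nonempty numeric vectors.
#' @return The statistic, in \[0, 1\].
#' @export
ks_statistic <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA", call. = FALSE)
  pooled <- sort(unique(c(a, b)))
  fa <- cumsum(tabulate(findInterval(a, pooled), length(pooled))) / length(a)
  fb <- cumsum(tabulate(findInterval(b, pooled), length(pooled))) / length(b)
  max(abs(fa - fb))
}
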