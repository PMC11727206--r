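# Estimators and risk mathematics: difference in means, MSE decomposition,
# maximum (worst-case) risk, randomization variance, percent reduction.

#' Bounds defining the minimax function class
#'
#' The worst-case risk is taken over outcome mean functions with RKHS norm
#' at most \eqn{\gamma} (in the space reproduced by `kernel`) and
#' conditional variances bounded by \eqn{\sigma^2}.
#'
#' @param sigma2 Variance bound \eqn{\sigma^2 \ge 0}.
#' @param gamma2 Squared RKHS-norm bound \eqn{\gamma^2 \ge 0}.
#' @param kernel A [kernel_spec][energy_kernel] object.
#' @return An object of class `risk_params`.
#' @export
risk_params <- function(sigma2 = 1, gamma2 = 1, kernel = energy_kernel()) {
  stopifnot(is.numeric(sigma2), is.finite(sigma2), sigma2 >= 0,
            is.numeric(gamma2), is.finite(gamma2), gamma2 >= 0,
            inherits(kernel, "kernel_spec"))
  structure(list(sigma2 = sigma2, gamma2 = gamma2, kernel = kernel),
            class = "risk_params")
}

#' Difference-in-means estimator
#'
#' \eqn{\hat\tau = n_1^{-1}\sum_j T_j Y_j - n_0^{-1}\sum_j (1 - T_j) Y_j}.
#'
#' @param treatment 0/1 vector.
#' @param y Outcome vector of the same length.
#' @return The treated mean minus the control mean.
#' @export
difference_in_means <- function(treatment, y) {
  treatment <- check_assignment(treatment)
  if (length(y) != length(treatment)) {
    stop("`y` and `treatment` lengths differ", call. = FALSE)
  }
  if (anyNA(y) || any(!is.finite(y))) stop("`y` must be finite", call. = FALSE)
  mean(y[treatment == 1L]) - mean(y[treatment == 0L])
}

#' Finite-sample average treatment effect of an outcome model
#'
#' \eqn{\tau = n^{-1}\sum_i \{f_1(X_i) - f_0(X_i)\}}, the average of the
#' conditional-mean treatment effects over the study units.
#'
#' @param X Covariate matrix.
#' @param model An [outcome_model()].
#' @return The average treatment effect.
#' @export
true_ate <- function(X, model) {
  X <- as_covariate_matrix(X)
  stopifnot(inherits(model, "outcome_model"))
  f1 <- model$f1(X); f0 <- model$f0(X)
  if (any(!is.finite(f1)) || any(!is.finite(f0))) {
    stop("outcome mean functions returned non-finite values", call. = FALSE)
  }
  mean(f1 - f0)
}

#' Conditional MSE decomposition of the difference-in-means estimator
#'
#' Given the true outcome model, decomposes
#' \eqn{E\{(\hat\tau - \tau)^2 \mid T, X\}} into the variance term
#' \eqn{V = n_1^{-2}\sum_j T_j \sigma_1^2(X_j) + n_0^{-2}\sum_j (1-T_j)\sigma_0^2(X_j)}
#' and the squared bias
#' \eqn{B = \{n_1^{-1}\sum_j T_j f_1(X_j) - n_0^{-1}\sum_j (1-T_j) f_0(X_j) - \tau\}^2}.
#'
#' @param treatment 0/1 vector.
#' @param X Covariate matrix.
#' @param model An [outcome_model()].
#' @return List with elements `variance` (V), `bias2` (B) and `mse` (V + B).
#' @export
conditional_mse <- function(treatment, X, model) {
  X <- as_covariate_matrix(X)
  treatment <- check_assignment(treatment, nrow(X))
  stopifnot(inherits(model, "outcome_model"))
  n1 <- sum(treatment); n0 <- length(treatment) - n1
  t1 <- treatment == 1L
  V <- sum(model$s1sq(X)[t1]) / n1^2 + sum(model$s0sq(X)[!t1]) / n0^2
  contrast <- mean(model$f1(X)[t1]) - mean(model$f0(X)[!t1])
  B <- (contrast - true_ate(X, model))^2
  list(variance = V, bias2 = B, mse = V + B)
}

#' Worst-case (maximum) risk of an assignment
#'
#' The worst-case MSE of the difference-in-means estimator over the
#' kernel-bounded outcome class:
#' \deqn{R(T) = \sigma^2 (n_1^{-1} + n_0^{-1}) + \gamma^2 D_K(X_1, X_0)^2.}
#' The bias component is computed from the group-vs-group discrepancy; the
#' equivalent full-set form
#' \eqn{\gamma^2 \{D_K(X_1, X) + D_K(X_0, X)\}^2} is available via
#' `form = "full"` and agrees up to floating point (the two-group empirical
#' CDFs mix to the full-set one in balanced proportions).
#'
#' @param treatment 0/1 vector.
#' @param X Covariate matrix.
#' @param params A [risk_params()] object.
#' @param form `"group"` (default) or `"full"`.
#' @return List of class `risk_report` with `variance_component`,
#'   `bias_component` and `total`.
#' @export
max_risk <- function(treatment, X, params, form = c("group", "full")) {
  form <- match.arg(form)
  X <- as_covariate_matrix(X)
  treatment <- check_assignment(treatment, nrow(X))
  stopifnot(inherits(params, "risk_params"))
  n1 <- sum(treatment); n0 <- length(treatment) - n1
  vc <- params$sigma2 * (1 / n1 + 1 / n0)
  X1 <- X[treatment == 1L, , drop = FALSE]
  X0 <- X[treatment == 0L, , drop = FALSE]
  bc <- if (form == "group") {
    params$gamma2 * discrepancy_between_groups(X1, X0, params$kernel)^2
  } else {
    params$gamma2 * (discrepancy_to_full(X1, X, params$kernel) +
                       discrepancy_to_full(X0, X, params$kernel))^2
  }
  structure(list(variance_component = vc, bias_component = bc,
                 total = vc + bc),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat("<risk_report>\n")
  cat(sprintf("  variance component: %.6g\n", x$variance_component))
  cat(sprintf("  bias component:     %.6g\n", x$bias_component))
  cat(sprintf("  total maximum risk: %.6g\n", x$total))
  invisible(x)
}

#' Randomization variance of the CRE difference-in-means estimator
#'
#' The variance of \eqn{\hat\tau} under complete randomization, decomposed
#' into the fixed-outcome (Neyman) part and the outcome-noise part:
#' \deqn{EV = n_1^{-1} S^2(f_1) + n_0^{-1} S^2(f_0) - n^{-1} S^2(f_1, f_0),}
#' \deqn{VE = (n n_1)^{-1} \sum_i \sigma_1^2(X_i) + (n n_0)^{-1} \sum_i \sigma_0^2(X_i),}
#' with \eqn{S^2(f_t) = (n-1)^{-1}\sum_i \{f_t(X_i) - \bar f_t\}^2} and
#' \eqn{S^2(f_1, f_0) = (n-1)^{-1}\sum_i (\tau_i - \tau)^2},
#' \eqn{\tau_i = f_1(X_i) - f_0(X_i)}.
#'
#' @param X Covariate matrix.
#' @param model An [outcome_model()].
#' @param n1 Number of treated units.
#' @return List with elements `EV`, `VE`, and `total`.
#' @export
randomization_variance <- function(X, model, n1 = ceiling(nrow(X) / 2)) {
  X <- as_covariate_matrix(X)
  stopifnot(inherits(model, "outcome_model"))
  n <- nrow(X); n1 <- as.integer(n1); n0 <- n - n1
  if (n1 < 1L || n1 > n - 1L) {
    stop("`n1` must satisfy 1 <= n1 <= n - 1", call. = FALSE)
  }
  f1 <- model$f1(X); f0 <- model$f0(X)
  EV <- var(f1) / n1 + var(f0) / n0 - var(f1 - f0) / n
  VE <- sum(model$s1sq(X)) / (n * n1) + sum(model$s0sq(X)) / (n * n0)
  list(EV = EV, VE = VE, total = EV + VE)
}

#' Exact assignment moments of the difference-in-means estimator
#'
#' Enumerates all \eqn{\binom{n}{n_1}} assignments and returns the exact
#' mean and variance of \eqn{\hat\tau} applied to the conditional-mean
#' outcomes; with noisy models the analytic noise term VE is added to the
#' variance. The mean equals the average treatment effect (unbiasedness of
#' the CRE), and the variance equals `randomization_variance()` exactly.
#' Guarded to n <= 14.
#'
#' @param X Covariate matrix with n <= 14 rows.
#' @param model An [outcome_model()].
#' @param n1 Number of treated units.
#' @return List with elements `mean` and `variance`.
#' @export
enumerate_assignment_moments <- function(X, model, n1 = ceiling(nrow(X) / 2)) {
  X <- as_covariate_matrix(X)
  stopifnot(inherits(model, "outcome_model"))
  n <- nrow(X); n1 <- as.integer(n1)
  if (n > 14L) {
    stop("enumeration is limited to n <= 14 units", call. = FALSE)
  }
  if (n1 < 1L || n1 > n - 1L) {
    stop("`n1` must satisfy 1 <= n1 <= n - 1", call. = FALSE)
  }
  f1 <- model$f1(X); f0 <- model$f0(X)
  sets <- combn(n, n1)
  tauhats <- apply(sets, 2L, function(tr) {
    mean(f1[tr]) - mean(f0[-tr])
  })
  VE <- sum(model$s1sq(X)) / (n * n1) + sum(model$s0sq(X)) / (n * (n - n1))
  list(mean = mean(tauhats),
       variance = mean((tauhats - mean(tauhats))^2) + VE)
}

#' Percent reduction in MSE relative to complete randomization
#'
#' \eqn{PR = 100 \{var(\hat\tau_{cre}) - MSE(\hat\tau_{mode})\} / var(\hat\tau_{cre})};
#' negative when the deterministic design underperforms.
#'
#' @param var_cre Randomization variance (or empirical MSE) of the CRE.
#' @param mse_mode MSE of the comparator design.
#' @return Percent reduction (may exceed 0..100 bounds only downward).
#' @export
percent_reduction <- function(var_cre, mse_mode) {
  if (!is.numeric(var_cre) || var_cre <= 0) {
    stop("`var_cre` must be positive", call. = FALSE)
  }
  100 * (var_cre - mse_mode) / var_cre
}

#' Variance-reduction factor of balanced Mahalanobis re-randomization
#'
#' \eqn{v_a = P(\chi^2_{p+2} \le a) / P(\chi^2_p \le a)}, the factor by
#' which accepting only assignments with Mahalanobis imbalance below `a`
#' shrinks the covariate-explained part of the randomization variance.
#' Lies in (0, 1) for finite `a` and increases to 1 as `a` grows.
#'
#' @param p Covariate dimension.
#' @param a Positive acceptance threshold.
#' @return The factor \eqn{v_a}.
#' @export
va_factor <- function(p, a) {
  p <- as.integer(p)
  if (p < 1L) stop("`p` must be at least 1", call. = FALSE)
  if (!is.numeric(a) || a <= 0) stop("`a` must be positive", call. = FALSE)
  pchisq(a, df = p + 2) / pchisq(a, df = p)
}
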