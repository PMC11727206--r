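# Replication engine: empirical MSE and Kolmogorov-Smirnov comparisons of
# assignment designs under the benchmark outcome models.

#' Design specifications for a simulation study
#'
#' Describes one assignment-generating design to be compared in
#' [run_study()].
#'
#' @param name One of `"cre"`, `"rem"`, `"mode"`, `"mode_relaxed"`, or
#'   `"external"`.
#' @param kernel Kernel for the discrepancy-based designs (default energy).
#' @param acceptance For `"rem"`, the target acceptance probability of the
#'   chi-square threshold (default 0.2); for `"mode_relaxed"`, the
#'   discrepancy-quantile level alpha (default 0.1).
#' @param M Monte Carlo budget for the user-kernel MODE branch.
#' @param n_quantile_draws Quantile-estimation budget for
#'   `"mode_relaxed"`.
#' @param assignment Fixed 0/1 vector for `"external"` designs (e.g. an
#'   assignment produced by another tool, read with [read_assignment()]).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(name = c("cre", "rem", "mode", "mode_relaxed", "external"),
                        kernel = energy_kernel(), acceptance = NULL,
                        M = 500L, n_quantile_draws = 1000L,
                        assignment = NULL) {
  name <- match.arg(name)
  if (name == "rem") acceptance <- acceptance %||% 0.2
  if (name == "mode_relaxed") acceptance <- acceptance %||% 0.1
  if (!is.null(acceptance) && (acceptance <= 0 || acceptance > 1)) {
    stop("`acceptance` must lie in (0, 1]", call. = FALSE)
  }
  if (name == "external" && is.null(assignment)) {
    stop("external designs need an `assignment` vector", call. = FALSE)
  }
  structure(list(name = name, kernel = kernel, acceptance = acceptance,
                 M = as.integer(M),
                 n_quantile_draws = as.integer(n_quantile_draws),
                 assignment = assignment),
            class = "design_spec")
}

#' Simulation study configuration
#'
#' @param n Units per replication (even for the balanced designs).
#' @param p Covariate dimension.
#' @param law Covariate law, `"uniform"` (U\[-3,3\]) or `"normal"`
#'   (N(0, 3), variance 3).
#' @param model An [outcome_model()] or a model id string.
#' @param designs Named list of [design_spec()]s; the names label the
#'   output rows. Percent reductions are reported against the design named
#'   `"cre"` when present.
#' @param replications Number of Monte Carlo replications.
#' @param seed Master seed; per-replication seeds are derived from it so
#'   all designs within a replication share the same covariate and noise
#'   draws (paired comparison).
#' @param redraw_covariates Redraw X each replication (default) or hold the
#'   first draw fixed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n, p, law = "uniform", model = "C1",
                       designs = list(cre = design_spec("cre"),
                                      mode = design_spec("mode")),
                       replications = 1000L, seed = 1L,
                       redraw_covariates = TRUE) {
  if (is.character(model)) model <- outcome_model(model)
  stopifnot(inherits(model, "outcome_model"))
  if (length(designs) < 1L || is.null(names(designs)) ||
      any(names(designs) == "")) {
    stop("`designs` must be a nonempty named list", call. = FALSE)
  }
  ok <- vapply(designs, inherits, logical(1), what = "design_spec")
  if (!all(ok)) stop("all designs must be design_spec objects", call. = FALSE)
  replications <- as.integer(replications)
  if (replications < 1L) stop("`replications` must be >= 1", call. = FALSE)
  structure(list(n = as.integer(n), p = as.integer(p),
                 law = match.arg(law, c("uniform", "normal")), model = model,
                 designs = designs, replications = replications,
                 seed = as.integer(seed),
                 redraw_covariates = isTRUE(redraw_covariates)),
            class = "sim_config")
}

generate_assignment <- function(spec, X, seed) {
  n <- nrow(X)
  switch(spec$name,
    cre = cre_assign(n, ceiling(n / 2), seed = seed),
    rem = rem_assign(X, rem_threshold(ncol(X), spec$acceptance), seed = seed),
    mode = mode_assign(X, spec$kernel, M = spec$M, seed = seed),
    mode_relaxed = relaxed_rerandomize(X, spec$kernel,
                                       alpha = spec$acceptance,
                                       n_quantile_draws = spec$n_quantile_draws,
                                       seed = seed),
    external = check_assignment(spec$assignment, n)
  )
}

#' Run a replication study
#'
#' For each replication: (re)draw the covariates, generate each design's
#' assignment, draw the potential outcomes, and record the estimation error
#' \eqn{\hat\tau - \tau} and the Kolmogorov-Smirnov distance between the
#' empirical distribution of all units' treated-arm potential outcomes and
#' that of the observed treated-group outcomes. \eqn{\tau} is the realized
#' finite-sample average treatment effect
#' \eqn{n^{-1}\sum_i \{Y_i(1) - Y_i(0)\}} of the replication (for the
#' noiseless models this equals the conditional-mean average effect).
#' Designs within a replication share the covariate and noise draws, so the
#' comparison is paired.
#'
#' @param config A [sim_config()].
#' @return An object of class `simulation_result`: a summary data frame
#'   (`$summary`) with empirical MSE (natural scale and x 10^4), mean KS
#'   (natural scale and x 10^2), Monte Carlo standard errors, and percent
#'   reduction versus the `"cre"` design; plus per-replication error and KS
#'   matrices (`$errors`, `$ks`).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  R <- config$replications
  dn <- names(config$designs)
  seeds <- matrix(derive_seeds(config$seed, 3L * R), nrow = R)
  errors <- matrix(NA_real_, R, length(dn), dimnames = list(NULL, dn))
  ksmat <- matrix(NA_real_, R, length(dn), dimnames = list(NULL, dn))
  failures <- character(0)
  X_fixed <- if (!config$redraw_covariates) {
    gen_covariates(config$n, config$p, config$law, seed = seeds[1L, 1L])
  } else {
    NULL
  }
  for (r in seq_len(R)) {
    res <- tryCatch({
      X <- X_fixed %||%
        gen_covariates(config$n, config$p, config$law, seed = seeds[r, 1L])
      vals <- eval_model(config$model, X)
      uv <- with_seed(seeds[r, 2L], list(u = rnorm(config$n),
                                         v = rnorm(config$n)))
      y1 <- vals$f1 + sqrt(vals$s1sq) * uv$u
      y0 <- vals$f0 + sqrt(vals$s0sq) * uv$v
      tau <- mean(y1 - y0)
      err <- numeric(length(dn)); ks <- numeric(length(dn))
      for (d in seq_along(dn)) {
        dseed <- (seeds[r, 3L] + d) %% (.Machine$integer.max - 1L)
        treatment <- generate_assignment(config$designs[[d]], X, dseed)
        yobs <- ifelse(treatment == 1L, y1, y0)
        err[d] <- difference_in_means(treatment, yobs) - tau
        ks[d] <- ks_statistic(y1, yobs[treatment == 1L])
      }
      list(err = err, ks = ks)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replication %d: %s", r, conditionMessage(res)))
    } else {
      errors[r, ] <- res$err
      ksmat[r, ] <- res$ks
    }
  }
  if (length(failures) > 0.01 * R) {
    stop(sprintf("run_study(): %d of %d replications failed; first: %s",
                 length(failures), R, failures[1L]), call. = FALSE)
  }
  ok <- !is.na(errors[, 1L])
  mse <- colMeans(errors[ok, , drop = FALSE]^2)
  mse_se <- apply(errors[ok, , drop = FALSE]^2, 2L, sd) / sqrt(sum(ok))
  mean_ks <- colMeans(ksmat[ok, , drop = FALSE])
  ks_se <- apply(ksmat[ok, , drop = FALSE], 2L, sd) / sqrt(sum(ok))
  pr <- if ("cre" %in% dn) 100 * (mse[["cre"]] - mse) / mse[["cre"]] else rep(NA_real_, length(dn))
  summary <- data.frame(
    design = dn,
    mse = unname(mse),
    mse_se = unname(mse_se),
    mse_x1e4 = unname(mse) * 1e4,
    mean_ks = unname(mean_ks),
    ks_se = unname(ks_se),
    ks_x1e2 = unname(mean_ks) * 1e2,
    pr_vs_cre = unname(pr),
    replications = sum(ok),
    row.names = NULL
  )
  structure(list(summary = summary, errors = errors[ok, , drop = FALSE],
                 ks = ksmat[ok, , drop = FALSE], config = config,
                 failures = failures),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<simulation_result: model %s, n = %d, p = %d, %s covariates, %d replications>\n",
              cfg$model$id, cfg$n, cfg$p, cfg$law,
              x$summary$replications[1L]))
  df <- x$summary
  disp <- data.frame(design = df$design,
                     `MSE x 1e4` = round(df$mse_x1e4, 1),
                     `KS x 1e2` = round(df$ks_x1e2, 2),
                     `PR vs CRE (%)` = round(df$pr_vs_cre),
                     check.names = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Tidy per-design metrics of a simulation result
#'
#' @param result A `simulation_result`.
#' @return Long-format data frame with columns `design`, `metric`, `value`,
#'   `mc_se` suitable for CSV export.
#' @export
tidy_simulation <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  df <- result$summary
  out <- rbind(
    data.frame(design = df$design, metric = "mse", value = df$mse,
               mc_se = df$mse_se),
    data.frame(design = df$design, metric = "mean_ks", value = df$mean_ks,
               mc_se = df$ks_se),
    data.frame(design = df$design, metric = "pr_vs_cre",
               value = df$pr_vs_cre, mc_se = NA_real_)
  )
  out[order(out$design, out$metric), , drop = FALSE]
}
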