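# Internal helpers: input validation and seeded evaluation.

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# stream. All exported stochastic functions route their randomness through
# this, so results are a pure function of their arguments.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Per-replication seeds derived from a master seed; independent of the
# caller's RNG state and always below .Machine$integer.max.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k, replace = FALSE))
}

as_covariate_matrix <- function(X, arg = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, ncol = 1L)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("`%s` must be a numeric matrix of covariates", arg), call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop(sprintf("`%s` contains missing or non-finite entries", arg), call. = FALSE)
  }
  if (nrow(X) < 2L) stop(sprintf("`%s` needs at least 2 units", arg), call. = FALSE)
  if (ncol(X) < 1L) stop(sprintf("`%s` needs at least 1 covariate", arg), call. = FALSE)
  storage.mode(X) <- "double"
  X
}

check_assignment <- function(treatment, n = NULL) {
  treatment <- as.integer(treatment)
  if (anyNA(treatment) || !all(treatment %in% c(0L, 1L))) {
    stop("`treatment` must be a vector of 0/1 labels", call. = FALSE)
  }
  n1 <- sum(treatment)
  if (n1 < 1L || n1 > length(treatment) - 1L) {
    stop("both treatment groups must be nonempty", call. = FALSE)
  }
  if (!is.null(n) && length(treatment) != n) {
    stop(sprintf("`treatment` has length %d but %d units were given",
                 length(treatment), n), call. = FALSE)
  }
  treatment
}

`%||%` <- function(a, b) if (is.null(a)) b else a
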