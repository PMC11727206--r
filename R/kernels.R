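# Reproducing kernels for the generalized discrepancy.

#' Kernel specifications
#'
#' A kernel specification couples a symmetric, real-valued kernel
#' \eqn{K(x, y)} on covariate space with the metadata the partition
#' optimizers need to dispatch fast paths. Two named kernels are provided:
#'
#' * `energy_kernel()`: \eqn{K(x, y) = -\|x - y\|_2}, the (negative
#'   Euclidean distance) kernel whose induced discrepancy is the energy
#'   distance between the two empirical distributions. Valid on all of
#'   \eqn{R^p}.
#' * `centered_l2_kernel()`:
#'   \eqn{K(x, y) = \prod_j (1 + 0.5|x_j - 0.5| + 0.5|y_j - 0.5| -
#'   0.5|x_j - y_j|)}, the kernel of the centered \eqn{L_2}-discrepancy from
#'   quasi-Monte Carlo theory. Defined on the unit cube \eqn{[0,1]^p}; pair
#'   it with [dds_split()] (marginal CDF transform) for unbounded data.
#' * `user_kernel()`: any user-supplied symmetric kernel function of two
#'   p-vectors, e.g. a discrete-covariate kernel. Discrepancies with user
#'   kernels fall back to plain R evaluation, and [mode_assign()] optimizes
#'   them by Monte Carlo search.
#'
#' @param eval A function `function(x, y)` returning a single finite
#'   numeric; must be symmetric in its arguments.
#' @param name Label for printing.
#' @param domain_note Free-text note on the kernel's domain of validity.
#' @return An object of class `kernel_spec` with fields `kind`, `eval`, and
#'   `domain_note`.
#' @examples
#' k <- energy_kernel()
#' k$eval(c(0, 0), c(3, 4))  # -5
#' @export
energy_kernel <- function() {
  structure(
    list(kind = "energy", eval = kernel_energy,
         domain_note = "all of R^p"),
    class = "kernel_spec"
  )
}

#' @rdname energy_kernel
#' @export
centered_l2_kernel <- function() {
  structure(
    list(kind = "centered_l2", eval = kernel_centered_l2,
         domain_note = "unit cube [0,1]^p"),
    class = "kernel_spec"
  )
}

#' @rdname energy_kernel
#' @export
user_kernel <- function(eval, name = "user", domain_note = "user-defined") {
  stopifnot(is.function(eval))
  structure(
    list(kind = "user", eval = eval, name = name, domain_note = domain_note),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec: %s (domain: %s)>\n",
              x$name %||% x$kind, x$domain_note))
  invisible(x)
}

#' Energy-distance kernel evaluation
#'
#' The negated Euclidean distance \eqn{K(x, y) = -\{\sum_j (x_j - y_j)^2\}^{1/2}}.
#' Always nonpositive, and zero exactly when `x == y`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single numeric value.
#' @examples
#' kernel_energy(c(0, 0), c(3, 4))  # -5
#' @export
kernel_energy <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("kernel inputs must be finite", call. = FALSE)
  }
  -sqrt(sum((x - y)^2))
}

#' Centered L2-discrepancy kernel evaluation
#'
#' \eqn{K(x, y) = \prod_j (1 + 0.5|x_j - 0.5| + 0.5|y_j - 0.5| - 0.5|x_j - y_j|)}
#' for `x`, `y` in the unit cube.
#'
#' @param x,y Numeric vectors of equal length with all coordinates in
#'   \eqn{[0, 1]}.
#' @return A single numeric value (nonnegative).
#' @examples
#' kernel_centered_l2(0.5, 0.5)  # 1
#' kernel_centered_l2(0, 1)      # 1
#' @export
kernel_centered_l2 <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (any(x < 0 | x > 1) || any(y < 0 | y > 1)) {
    stop("centered L2 kernel requires coordinates in [0, 1]", call. = FALSE)
  }
  prod(1 + 0.5 * abs(x - 0.5) + 0.5 * abs(y - 0.5) - 0.5 * abs(x - y))
}

# Full n x n Gram matrix of kernel values for the rows of X, using the
# compiled fast path for the named kernels.
kernel_gram <- function(kernel, X) {
  X <- as_covariate_matrix(X)
  switch(kernel$kind,
    energy = gram_energy_cpp(X),
    centered_l2 = {
      check_unit_cube(X)
      gram_centered_l2_cpp(X)
    },
    gram_r(kernel, X, X)
  )
}

# Cross Gram matrix between the rows of X and the rows of Y.
kernel_cross_gram <- function(kernel, X, Y) {
  X <- as_one_group(X, "X"); Y <- as_one_group(Y, "Y")
  if (ncol(X) != ncol(Y)) stop("covariate dimensions differ", call. = FALSE)
  switch(kernel$kind,
    energy = cross_gram_energy_cpp(X, Y),
    centered_l2 = {
      check_unit_cube(X); check_unit_cube(Y)
      cross_gram_centered_l2_cpp(X, Y)
    },
    gram_r(kernel, X, Y)
  )
}

gram_r <- function(kernel, X, Y) {
  n <- nrow(X); m <- nrow(Y)
  G <- matrix(0, n, m)
  for (i in seq_len(n)) {
    xi <- X[i, ]
    for (j in seq_len(m)) {
      v <- kernel$eval(xi, Y[j, ])
      if (!is.finite(v)) stop("kernel returned a non-finite value", call. = FALSE)
      G[i, j] <- v
    }
  }
  G
}

check_unit_cube <- function(X) {
  if (any(X < 0 | X > 1)) {
    stop("centered L2 kernel requires all covariates in [0, 1]; ",
         "use dds_split() to transform unbounded data", call. = FALSE)
  }
  invisible(X)
}
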