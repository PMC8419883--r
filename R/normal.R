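#' Construct a multivariate normal distribution
#'
#' Bundles a mean vector and covariance matrix into a validated object used
#' throughout the package. The covariance must be symmetric positive
#' semidefinite; small asymmetries (up to `1e-8 * max|Sigma|`, e.g. from
#' serialization round trips) are removed by averaging with the transpose.
#' Operations that whiten the normal additionally require strictly positive
#' eigenvalues.
#'
#' @param mu Numeric mean vector of length `k`.
#' @param Sigma Numeric `k x k` covariance matrix (a scalar is accepted in
#'   one dimension).
#' @return An object of class `"nd_normal"`: a list with elements `mu`,
#'   `Sigma` and `k`.
#' @examples
#' nd_normal(c(0, 1), diag(2))
#' nd_normal(0, 2)      # 1d, variance 2
#' @export
nd_normal <- function(mu, Sigma) {
  mu <- as.numeric(mu)
  if (length(mu) < 1L || any(!is.finite(mu)))
    stop("'mu' must be a finite numeric vector")
  Sigma <- as_matrix(Sigma)
  k <- length(mu)
  if (!all(dim(Sigma) == c(k, k)))
    stop("dimension mismatch: length(mu) = ", k, " but dim(Sigma) = ",
         paste(dim(Sigma), collapse = " x "))
  Sigma <- check_symmetric(Sigma, "Sigma")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("'Sigma' is not positive semidefinite (eigenvalue ",
         format(min(ev)), ")")
  structure(list(mu = mu, Sigma = Sigma, k = k), class = "nd_normal")
}

#' @export
print.nd_normal <- function(x, ...) {
  cat(sprintf("%dd normal distribution\n", x$k))
  cat("mu:   ", paste(signif(x$mu, 5), collapse = "  "), "\n")
  cat("Sigma:\n")
  print(signif(x$Sigma, 5))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_matrix <- function(M) {
  if (is.null(dim(M))) {
    if (length(M) == 1L) M <- matrix(as.numeric(M), 1L, 1L)
    else stop("expected a matrix")
  }
  storage.mode(M) <- "double"
  M
}

## Symmetry check with averaging repair; tolerance relative to max|M|.
check_symmetric <- function(M, name = "matrix", tol = 1e-8) {
  scale <- max(abs(M), 1e-300)
  if (max(abs(M - t(M))) > tol * scale)
    stop("'", name, "' is not symmetric")
  (M + t(M)) / 2
}

#' Symmetric matrix square root
#'
#' Returns the unique symmetric positive-semidefinite `S` with
#' `S %*% S == Sigma`, computed by eigen-decomposition. Eigenvalues in
#' `[-1e-10 * max(eig), 0)` are clipped to zero; more negative eigenvalues
#' are an error. `S` plays the role of a multidimensional standard
#' deviation: `x = S z + mu` maps a standard normal `z` to `N(mu, Sigma)`.
#'
#' @param Sigma Symmetric positive-semidefinite matrix.
#' @return Symmetric PSD matrix of the same dimension.
#' @examples
#' sym_sqrt(diag(c(4, 9)))   # diag(2, 3)
#' @export
sym_sqrt <- function(Sigma) {
  Sigma <- check_symmetric(as_matrix(Sigma), "Sigma")
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- e$values
  floor_tol <- 1e-10 * max(abs(lam), 1)
  if (min(lam) < -floor_tol)
    stop("matrix is not positive semidefinite (eigenvalue ",
         format(min(lam)), ")")
  lam[lam < 0] <- 0
  S <- e$vectors %*% (sqrt(lam) * t(e$vectors))
  (S + t(S)) / 2
}

## Inverse of the symmetric square root; errors on (near-)singular input.
sym_sqrt_inv <- function(Sigma) {
  Sigma <- check_symmetric(as_matrix(Sigma), "Sigma")
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- e$values
  if (min(lam) <= 1e-12 * max(lam))
    stop("covariance is singular; whitening requires strictly positive ",
         "eigenvalues")
  e$vectors %*% ((1 / sqrt(lam)) * t(e$vectors))
}

#' Mahalanobis distance between two means
#'
#' Computes `sqrt((mu_a - mu_b)' Sigma^-1 (mu_a - mu_b))`, the
#' covariance-scaled separation of two mean vectors. For equal-covariance
#' normals this equals the discriminability index d'.
#'
#' @param mu_a,mu_b Numeric mean vectors of equal length.
#' @param Sigma Strictly positive-definite covariance matrix.
#' @return Nonnegative scalar.
#' @examples
#' mahal_dist(c(0, 0), c(3, 4), diag(2))  # 5
#' @export
mahal_dist <- function(mu_a, mu_b, Sigma) {
  mu_a <- as.numeric(mu_a); mu_b <- as.numeric(mu_b)
  if (length(mu_a) != length(mu_b)) stop("mean vectors differ in length")
  Sigma <- check_symmetric(as_matrix(Sigma), "Sigma")
  if (!all(dim(Sigma) == length(mu_a))) stop("dimension mismatch")
  d <- mu_a - mu_b
  v <- tryCatch(solve(Sigma, d),
                error = function(e) stop("singular covariance"))
  val <- sum(d * v)
  if (val < 0) val <- 0
  sqrt(val)
}

#' Sample from a multivariate normal
#'
#' @param n Number of draws.
#' @param normal An [nd_normal] object.
#' @return `n x k` matrix of draws.
#' @export
nd_sample <- function(n, normal) {
  stopifnot(inherits(normal, "nd_normal"))
  S <- sym_sqrt(normal$Sigma)
  z <- matrix(stats::rnorm(n * normal$k), n, normal$k)
  sweep(z %*% S, 2L, normal$mu, "+")
}

## Serialization ------------------------------------------------------------

#' Convert a normal to/from a plain list (JSON-compatible)
#'
#' `nd_to_list()` returns `list(mu = ..., Sigma = ...)`;
#' `nd_from_list()` rebuilds the validated object (also accepts the raw
#' result of `jsonlite::fromJSON` on such a list).
#'
#' @param normal An [nd_normal] object.
#' @param x A list with elements `mu` and `Sigma`.
#' @return A list, or an [nd_normal].
#' @export
nd_to_list <- function(normal) {
  stopifnot(inherits(normal, "nd_normal"))
  list(mu = normal$mu, Sigma = normal$Sigma)
}

#' @rdname nd_to_list
#' @export
nd_from_list <- function(x) {
  if (is.null(x$mu) || is.null(x$Sigma))
    stop("list must have elements 'mu' and 'Sigma'")
  nd_normal(as.numeric(x$mu), as_matrix(x$Sigma))
}
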