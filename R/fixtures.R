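#' Built-in demonstration domains and fields
#'
#' Reference domains used in examples and tests:
#'
#' * `domain_torus(a, b)` — the solid torus
#'   `a - (b - sqrt(x1^2 + x2^2))^2 - x3^2 > 0` in 3d (tube of radius
#'   `sqrt(a)` around a circle of radius `b` in the x1-x2 plane);
#' * `domain_polyhedron(k)` — the cross-polytope `sum_i |x_i| < 1`;
#' * `domain_two_circles(c, r)` — the union of two discs of radius `r`
#'   centred at `(+-c, 0)`;
#' * `field_trig()` — the scalar field `x1 sin(x2) - x2 cos(x1)`;
#' * `field_power()` — the scalar field `x^y` (evaluated as
#'   `exp(y log x)`; the first coordinate must stay positive over the
#'   traced region).
#'
#' All fields accept an `n x k` matrix of points and return a vector.
#'
#' @param a,b Torus shape parameters (`a`, `b > 0`).
#' @param k Dimension of the cross-polytope.
#' @param c,r Disc half-separation and radius.
#' @param m Trace radius passed to [implicit_domain()].
#' @return An `nint_domain`, or a plain field function for the `field_*`
#'   helpers.
#' @name builtin_domains
NULL

#' @rdname builtin_domains
#' @export
domain_torus <- function(a = 1, b = 2, m = 10) {
  stopifnot(a > 0, b > 0)
  implicit_domain(function(x)
    a - (b - sqrt(x[, 1]^2 + x[, 2]^2))^2 - x[, 3]^2, k = 3L, m = m)
}

#' @rdname builtin_domains
#' @export
domain_polyhedron <- function(k = 4L, m = 10) {
  implicit_domain(function(x) 1 - rowSums(abs(x)), k = as.integer(k), m = m)
}

#' @rdname builtin_domains
#' @export
domain_two_circles <- function(c = 0.75, r = 1) {
  disc <- function(cx)
    quad_domain(-diag(2), c(2 * cx, 0), r^2 - cx^2)
  domain_union(disc(-c), disc(c))
}

#' @rdname builtin_domains
#' @export
field_trig <- function() {
  function(x) x[, 1] * sin(x[, 2]) - x[, 2] * cos(x[, 1])
}

#' @rdname builtin_domains
#' @export
field_power <- function() {
  function(x) {
    x1 <- pmax(x[, 1], 1e-300)
    exp(x[, 2] * log(x1))
  }
}

#' The demonstration 3d normal paired with the torus domain
#'
#' A fixed correlated trivariate normal used in the torus integration
#' demonstrations and tests.
#'
#' @return An [nd_normal].
#' @export
demo_normal_3d <- function() {
  nd_normal(c(1.5, 0, 0.5),
            matrix(c(1.0, 0.5, 0.2,
                     0.5, 1.4, -0.3,
                     0.2, -0.3, 0.8), 3, 3))
}

#' Seeded random fixtures
#'
#' Deterministic generators for test and demonstration inputs. The same
#' seed always produces the same output.
#'
#' `fixture_normals()` draws `n_classes` random k-dimensional normals:
#' means standard normal, covariances random rotations of positive
#' diagonals (eigenvalues uniform on `[0.3, 2]`), so every covariance is
#' strictly positive definite with condition number at most ~7.
#'
#' `fixture_t_samples()` draws multivariate-t samples per class around
#' the same kind of random parameters (heavy tails, excess kurtosis for
#' small `df`), labeled by class.
#'
#' `fixture_skewed_samples()` draws a deliberately non-normal
#' (exponentiated-normal, i.e. coordinate-wise lognormal) first class and
#' a normal second class, for model-adequacy demonstrations.
#'
#' @param k Dimension.
#' @param n_classes Number of classes.
#' @param seed Integer seed.
#' @param n Samples per class.
#' @param df Degrees of freedom of the t distribution.
#' @param mu_scale Scale of the random mean offsets.
#' @return `fixture_normals`: list of [nd_normal]; the sample generators:
#'   `list(x = matrix, labels = factor)`.
#' @export
fixture_normals <- function(k = 2L, n_classes = 2L, seed = 1L,
                            mu_scale = 1) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  lapply(seq_len(n_classes), function(i) {
    mu <- stats::rnorm(k) * mu_scale
    Sigma <- random_spd(k)
    nd_normal(mu, Sigma)
  })
}

random_spd <- function(k, eig_range = c(0.3, 2)) {
  ev <- stats::runif(k, eig_range[1], eig_range[2])
  if (k == 1L) return(matrix(ev, 1, 1))
  Q <- qr.Q(qr(matrix(stats::rnorm(k * k), k)))
  Q %*% (ev * t(Q))
}

#' @rdname fixture_normals
#' @export
fixture_t_samples <- function(n = 500L, k = 2L, n_classes = 2L, df = 3,
                              seed = 1L, mu_scale = 1) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  xs <- list(); labs <- list()
  for (i in seq_len(n_classes)) {
    mu <- stats::rnorm(k) * mu_scale
    S <- sym_sqrt(random_spd(k))
    z <- matrix(stats::rnorm(n * k), n, k)
    u <- stats::rchisq(n, df) / df
    xi <- sweep((z / sqrt(u)) %*% S, 2L, mu, "+")
    xs[[i]] <- xi
    labs[[i]] <- rep(paste0("c", i), n)
  }
  list(x = do.call(rbind, xs), labels = factor(unlist(labs)))
}

#' @rdname fixture_normals
#' @export
fixture_skewed_samples <- function(n = 500L, k = 2L, seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  ## class a: coordinate-wise exponentiated normal (skewed); class b: normal
  za <- matrix(stats::rnorm(n * k, sd = 0.7), n, k)
  xa <- exp(za) - 1
  xb <- sweep(matrix(stats::rnorm(n * k, sd = 0.8), n, k), 2L,
              rep(2.5, k), "+")
  list(x = rbind(xa, xb),
       labels = factor(rep(c("a", "b"), each = n)))
}
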