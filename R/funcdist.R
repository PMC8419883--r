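#' Distribution of a scalar function of a normal vector
#'
#' Any scalar field `f(x)` of a normal vector can be treated as a decision
#' variable with a 1d distribution. Its cdf at `c` is the normal
#' probability of the domain `c - f(x) > 0`, computed by the ray-trace
#' method; the pdf is the numerical derivative of the cdf; the inverse cdf
#' is found by root finding. For quadratic `f` the generalized chi-square
#' route ([gx2_params()] + [gx2_cdf()]) gives the same answers and is
#' usually preferable.
#'
#' @param f Scalar field accepting an `n x k` matrix of points (rows =
#'   points) and returning a length-`n` vector.
#' @param normal An [nd_normal].
#' @param c Threshold value(s) of the function.
#' @param m Trace radius in whitened sd units (see [implicit_domain()]).
#' @param tol Absolute tolerance of each underlying normal integral
#'   (passed to [norm_prob()]).
#' @param ... Passed to [norm_prob()] (e.g. `method`, `n_rays`, `seed`).
#' @return `func_cdf`: probabilities `P(f(x) < c)`; `func_pdf`: densities;
#'   `func_inv`: quantile(s).
#' @examples
#' nl <- nd_normal(c(0, 0), diag(2))
#' f <- function(x) x[, 1] + x[, 2]
#' func_cdf(f, nl, 0)      # 0.5
#' @export
func_cdf <- function(f, normal, c, m = 10, tol = 1e-6, ...) {
  stopifnot(is.function(f), inherits(normal, "nd_normal"))
  vapply(c, function(cc) {
    dom <- implicit_domain(function(x) cc - f(x), k = normal$k, m = m)
    norm_prob(normal, dom, tol = tol, ...)$p
  }, 0)
}

#' @rdname func_cdf
#' @param h_rel Relative step of the central finite difference; the
#'   absolute step is `max(h_rel, h_rel * |c|)`. The default balances the
#'   truncation error of the difference against the jitter of the
#'   ray-traced cdf (about `tol`), which an overly small step would
#'   amplify.
#' @export
func_pdf <- function(f, normal, c, m = 10, h_rel = 1e-3, ...) {
  vapply(c, function(cc) {
    h <- max(h_rel, h_rel * abs(cc))
    d <- (func_cdf(f, normal, cc + h, m = m, ...) -
          func_cdf(f, normal, cc - h, m = m, ...)) / (2 * h)
    max(d, 0)
  }, 0)
}

#' @rdname func_cdf
#' @param p Probability(ies) strictly inside (0, 1).
#' @param interval Optional bracketing interval for the root search; by
#'   default it is grown geometrically from the function value at the
#'   mean.
#' @export
func_inv <- function(f, normal, p, m = 10, interval = NULL, ...) {
  stopifnot(all(p > 0), all(p < 1))
  vapply(p, function(pp) {
    if (is.null(interval)) {
      c0 <- f(matrix(normal$mu, 1))
      span <- max(1, abs(c0))
      lo <- c0 - span; hi <- c0 + span
      while (func_cdf(f, normal, lo, m = m, ...) > pp && span < 1e8) {
        span <- span * 2; lo <- c0 - span
      }
      span <- max(1, abs(c0))
      while (func_cdf(f, normal, hi, m = m, ...) < pp && span < 1e8) {
        span <- span * 2; hi <- c0 + span
      }
    } else {
      lo <- interval[1]; hi <- interval[2]
    }
    stats::uniroot(function(cc) func_cdf(f, normal, cc, m = m, ...) - pp,
                   c(lo, hi), tol = 1e-9 * max(1, abs(hi - lo)))$root
  }, 0)
}

#' Moments of a function of a normal vector
#'
#' Mean and standard deviation of `f(x)` computed from its cdf: the
#' quantile range `(p_lo, 1 - p_lo)` is located with [func_inv()], padded,
#' and `E g(X)` is evaluated by adaptive quadrature of `g` against the
#' numerically differentiated cdf.
#'
#' @inheritParams func_cdf
#' @param p_lo Tail probability delimiting the integration window.
#' @return `list(mean, sd, var)`.
#' @export
func_moments <- function(f, normal, m = 10, p_lo = 1e-6, ...) {
  qs <- func_inv(f, normal, c(p_lo, 0.5, 1 - p_lo), m = m, ...)
  pad <- 0.25 * (qs[3] - qs[1])
  lo <- qs[1] - pad
  hi <- qs[3] + pad
  ## integrate against the cdf: E X = hi - int F dc  - (lo-side), done as
  ## E X = lo + int (1 - F) dc ; E X^2 by parts similarly with weight 2c
  Fc <- function(cc) func_cdf(f, normal, cc, m = m, ...)
  m1 <- lo + stats::integrate(function(cc) vapply(cc, function(z) 1 - Fc(z), 0),
                              lo, hi, rel.tol = 1e-7,
                              subdivisions = 400L)$value
  ## second moment about lo: E (X-lo)^2 = int 2 (c-lo) (1-F) dc
  m2lo <- stats::integrate(function(cc) vapply(cc, function(z)
    2 * (z - lo) * (1 - Fc(z)), 0), lo, hi, rel.tol = 1e-7,
    subdivisions = 400L)$value
  v <- m2lo - (m1 - lo)^2
  list(mean = m1, sd = sqrt(max(v, 0)), var = max(v, 0), median = qs[2])
}

#' Joint distribution of two functions of a normal vector
#'
#' The joint cdf `P(f1 < c1, f2 < c2)` is the normal probability of the
#' intersection `min(c1 - f1, c2 - f2) > 0`; the joint pdf is the mixed
#' second difference of the joint cdf on a 2 x 2 cross stencil.
#'
#' @inheritParams func_cdf
#' @param f1,f2 Scalar fields (matrix in, vector out).
#' @param c1,c2 Threshold values.
#' @return Probability (`joint_cdf`) or density (`joint_pdf`).
#' @export
joint_cdf <- function(f1, f2, normal, c1, c2, m = 10, tol = 1e-6, ...) {
  dom <- implicit_domain(function(x) pmin(c1 - f1(x), c2 - f2(x)),
                         k = normal$k, m = m)
  norm_prob(normal, dom, tol = tol, ...)$p
}

#' @rdname joint_cdf
#' @export
joint_pdf <- function(f1, f2, normal, c1, c2, m = 10, h_rel = 0.02,
                      tol = 1e-7, ...) {
  h1 <- max(h_rel, h_rel * abs(c1))
  h2 <- max(h_rel, h_rel * abs(c2))
  Fpp <- joint_cdf(f1, f2, normal, c1 + h1, c2 + h2, m = m, tol = tol, ...)
  Fpm <- joint_cdf(f1, f2, normal, c1 + h1, c2 - h2, m = m, tol = tol, ...)
  Fmp <- joint_cdf(f1, f2, normal, c1 - h1, c2 + h2, m = m, tol = tol, ...)
  Fmm <- joint_cdf(f1, f2, normal, c1 - h1, c2 - h2, m = m, tol = tol, ...)
  max((Fpp - Fpm - Fmp + Fmm) / (4 * h1 * h2), 0)
}
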