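#' Integration and classification domains
#'
#' A domain is a region of k-space over which a normal is integrated or on
#' one side of which samples are classified. Three representations are
#' supported, all with the membership convention "inside where the domain
#' function is positive":
#'
#' * **quadratic** — `q(x) = x' Q2 x + q1' x + q0 > 0`, created by
#'   [quad_domain()];
#' * **implicit** — `f(x) > 0` for an arbitrary scalar field `f`, created
#'   by [implicit_domain()]; zeros along a ray are located numerically
#'   within a trace radius `m`;
#' * **explicit (ray-trace)** — a function that, given a ray origin and
#'   unit direction, directly returns the ray's initial sign and crossing
#'   points; created by [raytrace_domain()] and by the set operations
#'   [domain_invert()], [domain_intersect()], [domain_union()].
#'
#' @name domains
NULL

#' Quadratic domain
#'
#' @param Q2 Symmetric `k x k` matrix (small asymmetries are symmetrized
#'   by averaging with the transpose).
#' @param q1 Length-`k` vector.
#' @param q0 Scalar offset.
#' @return An object of class `nint_domain`, type `"quadratic"`.
#' @examples
#' ## the unit disc 1 - |x|^2 > 0
#' quad_domain(-diag(2), c(0, 0), 1)
#' @export
quad_domain <- function(Q2, q1, q0) {
  Q2 <- as_matrix(Q2)
  Q2 <- (Q2 + t(Q2)) / 2
  q1 <- as.numeric(q1)
  q0 <- as.numeric(q0)
  k <- length(q1)
  if (!all(dim(Q2) == c(k, k)))
    stop("dim(Q2) must match length(q1)")
  if (length(q0) != 1L || !all(is.finite(Q2)) || !all(is.finite(q1)) ||
      !is.finite(q0))
    stop("quadratic coefficients must be finite; q0 a scalar")
  structure(list(type = "quadratic", Q2 = Q2, q1 = q1, q0 = q0, k = k),
            class = "nint_domain")
}

#' Implicit domain f(x) > 0
#'
#' @param f Scalar field. Must accept an `n x k` matrix of points (rows =
#'   points) and return a length-`n` numeric vector.
#' @param k Dimension of the space.
#' @param m Trace radius in whitened standard deviations: ray crossings are
#'   searched within `(-m, m)`. The probability truncation error of the
#'   ray method is below the ray mass beyond `m` (about `2 * (1 -
#'   pchisq(m^2, k))`, i.e. ~1.5e-23 in 1d at the default `m = 10`).
#' @param n_scan Number of scan cells used to bracket sign changes along a
#'   ray before bisection refinement.
#' @return An object of class `nint_domain`, type `"implicit"`.
#' @export
implicit_domain <- function(f, k, m = 10, n_scan = 1000L) {
  stopifnot(is.function(f), m > 0, n_scan >= 10L)
  structure(list(type = "implicit", f = f, k = as.integer(k), m = m,
                 n_scan = as.integer(n_scan)),
            class = "nint_domain")
}

#' Explicit ray-trace domain
#'
#' @param trace Function of a ray origin `o` and unit direction `n`
#'   returning `list(psi = -1|0|1, roots = sorted numeric vector)`, where
#'   `psi` is the domain membership sign at the start of the ray (at
#'   `-Inf`) and `roots` are the signed distances along the ray at which
#'   membership flips.
#' @param k Dimension of the space.
#' @return An object of class `nint_domain`, type `"explicit"`.
#' @export
raytrace_domain <- function(trace, k) {
  stopifnot(is.function(trace))
  structure(list(type = "explicit", trace = trace, k = as.integer(k)),
            class = "nint_domain")
}

#' @export
print.nint_domain <- function(x, ...) {
  cat(sprintf("%s domain in %sd\n", x$type,
              if (is.null(x$k)) "?" else x$k))
  invisible(x)
}

## Evaluate a quadratic at points (rows of x) -------------------------------
quad_eval <- function(q, x) {
  x <- if (is.null(dim(x))) matrix(x, ncol = length(q$q1)) else x
  rowSums((x %*% q$Q2) * x) + drop(x %*% q$q1) + q$q0
}

## Evaluate domain membership function at points (rows); used by oracles
## and by set operations on implicit forms.
domain_eval <- function(domain, x) {
  switch(domain$type,
         quadratic = quad_eval(domain, x),
         implicit  = domain$f(if (is.null(dim(x))) matrix(x, nrow = 1) else x),
         stop("membership function not available for explicit domains"))
}

#' Whiten a quadratic domain
#'
#' Re-expresses `q(x) > 0` in the standardized coordinates
#' `z = S^-1 (x - mu)` of a normal, so that `q~(z) = q(S z + mu)`:
#' `Q2~ = S Q2 S`, `q1~ = 2 S Q2 mu + S q1`, `q0~ = q(mu)`.
#'
#' @param q A quadratic [quad_domain()].
#' @param normal An [nd_normal] with strictly positive-definite covariance.
#' @return The whitened quadratic domain.
#' @export
standardize_quadratic <- function(q, normal) {
  stopifnot(inherits(q, "nint_domain"), q$type == "quadratic",
            inherits(normal, "nd_normal"))
  if (q$k != normal$k) stop("dimension mismatch between domain and normal")
  S <- sym_sqrt(normal$Sigma)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) stop("singular covariance")
  mu <- normal$mu
  Q2t <- S %*% q$Q2 %*% S
  q1t <- drop(2 * S %*% q$Q2 %*% mu + S %*% q$q1)
  q0t <- drop(quad_eval(q, matrix(mu, 1)))
  quad_domain(Q2t, q1t, q0t)
}

## Ray tracing ---------------------------------------------------------------

#' Trace a domain along a ray
#'
#' Restricts a domain to the line `o + z n` (`z` from `-Inf` to `Inf`) and
#' returns the initial sign `psi` (+1 inside at `-Inf`, -1 outside, 0
#' grazing) and the sorted crossing points. Tangencies (even-multiplicity
#' zeros, where the domain function touches zero without changing sign)
#' are discarded since they do not change membership.
#'
#' @param domain An `nint_domain`.
#' @param o Ray origin (length-`k` vector).
#' @param n Unit direction vector.
#' @return `list(psi, roots)`.
#' @export
trace_ray <- function(domain, o, n) {
  stopifnot(inherits(domain, "nint_domain"))
  o <- as.numeric(o); n <- as.numeric(n)
  if (abs(sum(n^2) - 1) > 1e-8) stop("'n' must be a unit vector")
  tr <- switch(domain$type,
               quadratic = trace_quad(domain, o, n),
               implicit  = trace_implicit(domain, o, n),
               explicit  = domain$trace(o, n))
  tr$roots <- merge_close_roots(tr$roots)
  tr
}

sgn <- function(x, tol = 0) {
  ifelse(x > tol, 1, ifelse(x < -tol, -1, 0))
}

merge_close_roots <- function(r, tol = 1e-12) {
  if (length(r) < 2L) return(r)
  r <- sort(r)
  keep <- c(TRUE, diff(r) > tol)
  ## pairs of coincident roots cancel (tangency), so drop both
  if (all(keep)) return(r)
  out <- numeric(0)
  i <- 1L
  while (i <= length(r)) {
    j <- i
    while (j < length(r) && r[j + 1L] - r[j] <= tol) j <- j + 1L
    if ((j - i + 1L) %% 2L == 1L) out <- c(out, r[i])
    i <- j + 1L
  }
  out
}

## Quadratic restricted to a ray: q(o + z n) = a z^2 + b z + c.
trace_quad <- function(q, o, n) {
  a <- drop(crossprod(n, q$Q2 %*% n))
  b <- drop(2 * crossprod(n, q$Q2 %*% o) + crossprod(q$q1, n))
  c0 <- drop(quad_eval(q, matrix(o, 1)))
  scale <- max(abs(a), abs(b), abs(c0), 1e-300)
  tol <- 1e-14 * scale
  if (abs(a) > tol) {
    psi <- sgn(a)
    disc <- b^2 - 4 * a * c0
    roots <- if (disc > 0) {
      ## numerically stable quadratic roots
      s <- -(b + sign(b + (b == 0)) * sqrt(disc)) / 2
      r <- c(s / a, if (abs(s) > 0) c0 / s else -b / (2 * a))
      sort(r)
    } else numeric(0)       # tangent (double) roots are discarded
  } else if (abs(b) > tol) {
    psi <- -sgn(b)
    roots <- -c0 / b
  } else {
    psi <- sgn(c0)
    roots <- numeric(0)
  }
  list(psi = psi, roots = roots)
}

## Implicit field restricted to a ray: scan (-m, m) for sign changes, then
## refine each bracket by (vectorized) bisection.
trace_implicit <- function(domain, o, n, z_tol = 1e-10) {
  m <- domain$m
  zg <- seq(-m, m, length.out = domain$n_scan + 1L)
  ## keep nodes strictly inside (-m, m)
  zg[1L] <- -m + 1e-9 * m
  zg[length(zg)] <- m - 1e-9 * m
  pts <- outer(zg, n) + rep(o, each = length(zg))
  fv <- domain$f(pts)
  if (length(fv) != length(zg) || any(!is.finite(fv)))
    stop("implicit domain function returned non-finite or wrongly shaped ",
         "values on the ray (first bad z = ",
         if (length(fv) == length(zg)) format(zg[which(!is.finite(fv))[1]])
         else "?", ")")
  s <- sgn(fv)
  ## a zero value on the grid: nudge to the sign of a neighbour so the
  ## crossing is still caught by the adjacent bracket
  if (any(s == 0)) {
    nz <- which(s == 0)
    for (i in nz) s[i] <- if (i > 1L) s[i - 1L] else s[min(i + 1L, length(s))]
  }
  flips <- which(s[-1L] * s[-length(s)] < 0)
  roots <- numeric(0)
  if (length(flips)) {
    lo <- zg[flips]; hi <- zg[flips + 1L]
    flo <- fv[flips]
    it <- ceiling(log2((2 * m) / z_tol / domain$n_scan)) + 2L
    for (i in seq_len(max(it, 1L))) {
      mid <- (lo + hi) / 2
      fm <- domain$f(outer(mid, n) + rep(o, each = length(mid)))
      left <- flo * fm > 0
      lo[left] <- mid[left]; flo[left] <- fm[left]
      hi[!left] <- mid[!left]
      if (max(hi - lo) < z_tol) break
    }
    roots <- sort((lo + hi) / 2)
  }
  list(psi = s[1L], roots = roots)
}

## Set operations ------------------------------------------------------------

## membership state of a trace at position z (not at a root): psi * (-1)^crossed
trace_state <- function(tr, z) {
  tr$psi * (-1)^sum(tr$roots < z)
}

#' Set operations on domains
#'
#' Build complex domains from simpler ones. The result is an explicit
#' ray-trace domain: inversion flips the initial sign of every ray and
#' keeps the crossing points; intersection takes the minimum of the
#' initial signs and keeps each member's crossings at which every other
#' member is strictly inside; union is the inverted intersection of the
#' inversions. Membership matches `min`/`max` of the member domain
#' functions.
#'
#' @param domain,... `nint_domain` objects (at least two for
#'   intersect/union).
#' @return An explicit `nint_domain`.
#' @examples
#' disc <- function(cx) quad_domain(-diag(2), c(2 * cx, 0), 1 - cx^2)
#' lens <- domain_intersect(disc(-0.75), disc(0.75))
#' @export
domain_invert <- function(domain) {
  stopifnot(inherits(domain, "nint_domain"))
  k <- domain$k
  raytrace_domain(function(o, n) {
    tr <- trace_ray(domain, o, n)
    list(psi = -tr$psi, roots = tr$roots)
  }, k)
}

#' @rdname domain_invert
#' @export
domain_intersect <- function(...) {
  doms <- list(...)
  if (length(doms) == 1L && is.list(doms[[1L]]) &&
      !inherits(doms[[1L]], "nint_domain")) doms <- doms[[1L]]
  if (length(doms) < 1L) stop("need at least one domain")
  lapply(doms, function(d) stopifnot(inherits(d, "nint_domain")))
  if (length(doms) == 1L) return(doms[[1L]])
  k <- doms[[1L]]$k
  raytrace_domain(function(o, n) {
    trs <- lapply(doms, trace_ray, o = o, n = n)
    psi <- min(vapply(trs, `[[`, 0, "psi"))
    roots <- numeric(0)
    for (i in seq_along(trs)) {
      for (z in trs[[i]]$roots) {
        others_in <- all(vapply(seq_along(trs)[-i], function(j)
          trace_state(trs[[j]], z) > 0, TRUE))
        if (others_in) roots <- c(roots, z)
      }
    }
    list(psi = psi, roots = sort(roots))
  }, k)
}

#' @rdname domain_invert
#' @export
domain_union <- function(...) {
  doms <- list(...)
  if (length(doms) == 1L && is.list(doms[[1L]]) &&
      !inherits(doms[[1L]], "nint_domain")) doms <- doms[[1L]]
  if (length(doms) < 2L) stop("need at least two domains")
  domain_invert(domain_intersect(lapply(doms, domain_invert)))
}

## Serialization -------------------------------------------------------------

#' Convert a quadratic domain to/from a plain list
#' @param q A quadratic `nint_domain`.
#' @param x A list with elements `Q2`, `q1`, `q0`.
#' @return A list, or a quadratic domain.
#' @export
quad_to_list <- function(q) {
  stopifnot(inherits(q, "nint_domain"), q$type == "quadratic")
  list(Q2 = q$Q2, q1 = q$q1, q0 = q$q0)
}

#' @rdname quad_to_list
#' @export
quad_from_list <- function(x) {
  if (is.null(x$Q2) || is.null(x$q1) || is.null(x$q0))
    stop("list must have elements 'Q2', 'q1' and 'q0'")
  quad_domain(as_matrix(x$Q2), as.numeric(x$q1), as.numeric(x$q0))
}
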