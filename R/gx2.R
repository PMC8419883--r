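#' Generalized chi-square parameters of a quadratic form of a normal
#'
#' Any quadratic `q(x)` of a normal vector `x ~ N(mu, Sigma)` is
#' distributed as a generalized chi-square: a weighted sum of independent
#' noncentral chi-square variables plus an independent normal,
#' `sum_j w_j chi2'(k_j, lam_j) + N(m, s^2)`. The parameters are obtained
#' by whitening the quadratic and eigen-decomposing its matrix: the
#' weights `w` are the unique nonzero eigenvalues, `k` their
#' multiplicities, `lam_j = sum_{i: D_i = w_j} b_i^2 / (4 w_j^2)` with
#' `b = R' q1~`, `s` the norm of `b` over the null eigenvalues and
#' `m = q(mu) - sum_j w_j lam_j`.
#'
#' @param normal An [nd_normal] with strictly positive-definite covariance.
#' @param q A quadratic domain ([quad_domain()]).
#' @return An object of class `gx2_params`: list with `w`, `k`, `lam`,
#'   `m`, `s`.
#' @examples
#' ## x^2 with x ~ N(0,1) is a plain chi-square with 1 df
#' gx2_params(nd_normal(0, 1), quad_domain(1, 0, 0))
#' @export
gx2_params <- function(normal, q) {
  stopifnot(inherits(normal, "nd_normal"), inherits(q, "nint_domain"),
            q$type == "quadratic")
  if (normal$k != q$k) stop("dimension mismatch")
  qt <- standardize_quadratic(q, normal)
  e <- eigen(qt$Q2, symmetric = TRUE)
  D <- e$values
  b <- drop(crossprod(e$vectors, qt$q1))
  tol <- 1e-8 * max(abs(D), 1e-300)
  nz <- abs(D) > tol
  s <- sqrt(sum(b[!nz]^2))
  if (!any(nz)) {
    return(new_gx2(w = numeric(0), k = integer(0), lam = numeric(0),
                   m = qt$q0, s = s))
  }
  Dn <- D[nz]; bn <- b[nz]
  ## group eigenvalues equal within tolerance into one weight
  ord <- order(Dn)
  Dn <- Dn[ord]; bn <- bn[ord]
  grp <- cumsum(c(1, diff(Dn) > tol))
  w <- as.numeric(tapply(Dn, grp, mean))
  kk <- as.integer(tapply(Dn, grp, length))
  lam <- as.numeric(tapply(seq_along(Dn), grp, function(i)
    sum(bn[i]^2))) / (4 * w^2)
  m <- qt$q0 - sum(w * lam)
  new_gx2(w = w, k = kk, lam = lam, m = m, s = s)
}

#' Construct generalized chi-square parameters directly
#'
#' @param w Unique nonzero weights.
#' @param k Positive integer degrees of freedom (same length as `w`).
#' @param lam Noncentralities `>= 0` (same length as `w`).
#' @param m Offset of the independent normal term.
#' @param s Standard deviation (`>= 0`) of the independent normal term.
#' @return A `gx2_params` object.
#' @export
new_gx2 <- function(w = numeric(0), k = integer(0), lam = numeric(0),
                    m = 0, s = 0) {
  w <- as.numeric(w); k <- as.integer(k); lam <- as.numeric(lam)
  if (length(k) != length(w) || length(lam) != length(w))
    stop("'w', 'k' and 'lam' must have equal length")
  if (any(w == 0) || anyDuplicated(w))
    stop("weights must be unique and nonzero")
  if (any(k < 1L)) stop("degrees of freedom must be positive integers")
  if (any(lam < 0)) stop("noncentralities must be >= 0")
  if (s < 0) stop("'s' must be >= 0")
  structure(list(w = w, k = k, lam = lam, m = as.numeric(m),
                 s = as.numeric(s)), class = "gx2_params")
}

#' @export
print.gx2_params <- function(x, ...) {
  cat("generalized chi-square parameters\n")
  cat("  w:  ", paste(signif(x$w, 6), collapse = " "), "\n")
  cat("  k:  ", paste(x$k, collapse = " "), "\n")
  cat("  lam:", paste(signif(x$lam, 6), collapse = " "), "\n")
  cat(sprintf("  m: %g   s: %g\n", x$m, x$s))
  invisible(x)
}

#' Moments of a generalized chi-square
#'
#' Mean `sum w_j (k_j + lam_j) + m`; variance
#' `2 sum w_j^2 (k_j + 2 lam_j) + s^2`.
#'
#' @param params A `gx2_params` object.
#' @return Scalar mean / variance / sd.
#' @export
gx2_mean <- function(params) sum(params$w * (params$k + params$lam)) + params$m

#' @rdname gx2_mean
#' @export
gx2_var <- function(params) 2 * sum(params$w^2 * (params$k + 2 * params$lam)) +
  params$s^2

#' @rdname gx2_mean
#' @export
gx2_sd <- function(params) sqrt(gx2_var(params))

## Noncentral chi-square cdf with 1 df via the exact normal form
## P(chi2'_1(lam) <= x) = Phi(sqrt(x) - sqrt(lam)) - Phi(-sqrt(x) - sqrt(lam)).
## stats::pchisq with ncp only has absolute accuracy (~1e-12); this form
## keeps relative accuracy into the far tails (down to realmin), which the
## Bayes-error computations need for highly separated classes.
ncchisq1_cdf <- function(x, lam, lower = TRUE) {
  rx <- sqrt(pmax(x, 0)); rl <- sqrt(lam)
  if (lower) {
    out <- stats::pnorm(rx - rl) - stats::pnorm(-rx - rl)
    out[x <= 0] <- 0
    pmin(pmax(out, 0), 1)
  } else {
    out <- stats::pnorm(rx - rl, lower.tail = FALSE) +
      stats::pnorm(-rx - rl)
    out[x <= 0] <- 1
    pmin(pmax(out, 0), 1)
  }
}

## Imhof-type characteristic function inversion ------------------------------
## F(x) = 1/2 - (1/pi) Int_0^inf sin(theta(u)) / (u rho(u)) du
## f(x) = (1/pi)  Int_0^inf cos(theta(u)) / rho(u) du
## theta(u) = sum_j [k_j/2 atan(2 w_j u) + lam_j w_j u / (1 + 4 w_j^2 u^2)]
##            + u (m - x)
## rho(u)  = prod_j (1 + 4 w_j^2 u^2)^(k_j/4)
##           * exp(s^2 u^2 / 2 + sum_j 2 lam_j w_j^2 u^2 / (1 + 4 w_j^2 u^2))
gx2_theta_rho <- function(u, params, x) {
  w <- params$w; k <- params$k; lam <- params$lam
  theta <- u * (params$m - x)
  lrho <- params$s^2 * u^2 / 2
  for (j in seq_along(w)) {
    wu2 <- 1 + 4 * w[j]^2 * u^2
    theta <- theta + k[j] / 2 * atan(2 * w[j] * u) +
      lam[j] * w[j] * u / wu2
    lrho <- lrho + k[j] / 4 * log(wu2) + 2 * lam[j] * w[j]^2 * u^2 / wu2
  }
  list(theta = theta, lrho = lrho)
}

## Shared engine for the oscillatory inversion integrals. The integrand
## oscillates asymptotically with frequency |m - x|; we integrate over
## consecutive half-period blocks and accelerate the alternating block sums
## by iterated averaging (an Euler transformation), which converges to near
## machine precision with a few dozen blocks. When the asymptotic frequency
## is low the plain adaptive integral over a finite window (chosen from the
## amplitude decay) suffices.
gx2_imhof <- function(x, params, kind = c("cdf", "pdf"), abs_tol = 1e-10) {
  kind <- match.arg(kind)
  integrand <- function(u) {
    u <- pmax(u, 1e-300)
    tr <- gx2_theta_rho(u, params, x)
    if (kind == "cdf") sin(tr$theta) * exp(-tr$lrho) / u
    else cos(tr$theta) * exp(-tr$lrho)
  }
  log_amp <- function(u)
    -gx2_theta_rho(u, params, x)$lrho -
      (if (kind == "cdf") log(u) else 0)
  cc <- abs(params$m - x)
  w_min <- min(abs(params$w))
  settle <- 10 / w_min            # atan/noncentrality terms settled past here
  h <- if (cc > 0) pi / cc else Inf
  Ktot <- sum(params$k)

  ## window beyond which the remaining amplitude mass is below tolerance
  U <- settle
  decay <- max(Ktot / 2 - (kind == "pdf") + (kind == "cdf"), 0.25)
  while (exp(log_amp(U)) * U / decay > abs_tol && U < 1e9) U <- U * 2

  if (!is.finite(h) || U / h <= 60) {
    ## few oscillations inside the window: adaptive integral over panels
    ## growing geometrically from the settle scale (a single call over a
    ## huge range would let the quadrature overlook the mass near zero)
    edges <- settle * 2^(0:ceiling(max(log2(U / settle), 0)))
    edges <- c(0, pmin(edges, U))
    edges <- unique(edges)
    val <- 0
    for (j in seq_len(length(edges) - 1L)) {
      I <- stats::integrate(integrand, edges[j], edges[j + 1L],
                            abs.tol = abs_tol / length(edges),
                            rel.tol = abs_tol, subdivisions = 5000L,
                            stop.on.error = FALSE)
      if (!I$message %in% c("OK", "roundoff error was detected"))
        stop("characteristic-function inversion failed to converge: ",
             I$message)
      val <- val + I$value
    }
    return(val)
  }

  n_settle <- min(ceiling(settle / h), 440L)
  nb <- n_settle + 80L
  edges <- h * (0:nb)
  blocks <- vapply(seq_len(nb), function(j)
    stats::integrate(integrand, edges[j], edges[j + 1L],
                     rel.tol = 1e-10, abs.tol = abs_tol / 10,
                     subdivisions = 200L, stop.on.error = FALSE)$value, 0)
  v <- cumsum(blocks)[(nb - 40L):nb]   # partial sums including the head
  while (length(v) > 1L) v <- (v[-1L] + v[-length(v)]) / 2
  v
}

gx2_imhof_cdf <- function(x, params, abs_tol = 1e-10) {
  val <- 0.5 - gx2_imhof(x, params, "cdf", abs_tol) / pi
  min(max(val, 0), 1)
}

gx2_imhof_pdf <- function(x, params, abs_tol = 1e-10) {
  max(gx2_imhof(x, params, "pdf", abs_tol) / pi, 0)
}

#' Generalized chi-square distribution functions
#'
#' Cumulative distribution, density, quantile and random generation for
#' the generalized chi-square. Exact closed forms ([stats::pchisq] /
#' [stats::pnorm]) are used when the parameters reduce to a pure normal or
#' a single scaled noncentral chi-square (these paths retain full tail
#' accuracy); the general case inverts the characteristic function with an
#' Imhof-type oscillatory integral.
#'
#' @param x Quantile(s).
#' @param p Probability in (0, 1).
#' @param n Number of draws.
#' @param params A `gx2_params` object.
#' @param abs_tol Absolute tolerance of the inversion integral.
#' @param seed Optional integer seed.
#' @return Probabilities, densities, quantiles, or a numeric sample.
#' @examples
#' gx2_cdf(1, new_gx2(w = 1, k = 1, lam = 0))  # pchisq(1, 1)
#' @export
gx2_cdf <- function(x, params, abs_tol = 1e-10) {
  stopifnot(inherits(params, "gx2_params"))
  w <- params$w
  if (length(w) == 0L) {
    if (params$s == 0) return(as.numeric(x >= params$m))
    return(stats::pnorm(x, mean = params$m, sd = params$s))
  }
  if (length(w) == 1L && params$s == 0) {
    y <- (x - params$m) / w
    if (params$k == 1L) return(ncchisq1_cdf(y, params$lam, lower = w > 0))
    return(if (w > 0) stats::pchisq(y, params$k, ncp = params$lam)
           else stats::pchisq(y, params$k, ncp = params$lam,
                              lower.tail = FALSE))
  }
  vapply(x, gx2_imhof_cdf, 0, params = params, abs_tol = abs_tol)
}

#' @rdname gx2_cdf
#' @export
gx2_pdf <- function(x, params, abs_tol = 1e-10) {
  stopifnot(inherits(params, "gx2_params"))
  w <- params$w
  if (length(w) == 0L) {
    if (params$s == 0) stop("degenerate point mass has no density")
    return(stats::dnorm(x, mean = params$m, sd = params$s))
  }
  if (length(w) == 1L && params$s == 0) {
    y <- (x - params$m) / w
    d <- stats::dchisq(y, params$k, ncp = params$lam) / abs(w)
    d[!is.finite(d)] <- 0
    return(d)
  }
  vapply(x, gx2_imhof_pdf, 0, params = params, abs_tol = abs_tol)
}

#' @rdname gx2_cdf
#' @export
gx2_inv <- function(p, params, abs_tol = 1e-10) {
  stopifnot(inherits(params, "gx2_params"))
  vapply(p, function(pp) {
    if (pp <= 0 || pp >= 1) stop("p must be strictly inside (0, 1)")
    w <- params$w
    if (length(w) == 0L) {
      if (params$s == 0) return(params$m)
      return(stats::qnorm(pp, mean = params$m, sd = params$s))
    }
    if (length(w) == 1L && params$s == 0) {
      y <- if (w > 0) stats::qchisq(pp, params$k, ncp = params$lam)
           else stats::qchisq(pp, params$k, ncp = params$lam,
                              lower.tail = FALSE)
      return(params$m + w * y)
    }
    mu <- gx2_mean(params); sdv <- gx2_sd(params)
    lo <- mu - 10 * sdv; hi <- mu + 10 * sdv
    while (gx2_cdf(lo, params, abs_tol) > pp) lo <- mu - 2 * (mu - lo)
    while (gx2_cdf(hi, params, abs_tol) < pp) hi <- mu + 2 * (hi - mu)
    stats::uniroot(function(xx) gx2_cdf(xx, params, abs_tol) - pp,
                   c(lo, hi), tol = 1e-10 * max(1, sdv))$root
  }, 0)
}

#' @rdname gx2_cdf
#' @export
gx2_rand <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "gx2_params"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  out <- rep(params$m, n)
  for (j in seq_along(params$w))
    out <- out + params$w[j] *
      stats::rchisq(n, df = params$k[j], ncp = params$lam[j])
  if (params$s > 0) out <- out + stats::rnorm(n, sd = params$s)
  out
}

## Convenience: P(q(x) > 0) for a quadratic domain, via the generalized
## chi-square route. Retains closed-form tail accuracy when the whitened
## boundary is flat (probability Phi(q0~ / |q1~|)) or reduces to a single
## noncentral chi-square.
quad_prob_gx2 <- function(normal, q, abs_tol = 1e-10) {
  params <- gx2_params(normal, q)
  if (length(params$w) == 0L) {
    if (params$s == 0) return(as.numeric(params$m > 0))
    ## flat boundary: P(N(m, s^2) > 0) = Phi(m / s)
    return(stats::pnorm(params$m / params$s))
  }
  if (length(params$w) == 1L && params$s == 0) {
    y <- -params$m / params$w
    if (params$k == 1L)
      return(ncchisq1_cdf(y, params$lam, lower = params$w < 0))
    return(if (params$w > 0)
      stats::pchisq(y, params$k, ncp = params$lam, lower.tail = FALSE)
      else stats::pchisq(y, params$k, ncp = params$lam))
  }
  1 - gx2_cdf(0, params, abs_tol)
}

#' Convert generalized chi-square parameters to/from a plain list
#' @param params A `gx2_params` object.
#' @param x A list with elements `w`, `k`, `lam`, `m`, `s`.
#' @return A list, or a `gx2_params`.
#' @export
gx2_to_list <- function(params) {
  stopifnot(inherits(params, "gx2_params"))
  list(w = params$w, k = params$k, lam = params$lam, m = params$m,
       s = params$s)
}

#' @rdname gx2_to_list
#' @export
gx2_from_list <- function(x)
  new_gx2(w = x$w, k = x$k, lam = x$lam,
          m = if (is.null(x$m)) 0 else x$m,
          s = if (is.null(x$s)) 0 else x$s)
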