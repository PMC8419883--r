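#' Approximate discriminability indices d'_a and d'_e
#'
#' `d_a` is the Mahalanobis distance of the means under the pooled
#' covariance `(Sigma_a + Sigma_b)/2` (root-mean-square sd). `d_e` uses
#' the average of the symmetric sd matrices instead:
#' `|S_avg^-1 (mu_a - mu_b)|` with `S_avg = (S_a + S_b)/2`. In one
#' dimension these are `|mu_a - mu_b| / sigma_rms` and
#' `|mu_a - mu_b| / sigma_avg`. Always `d_a <= d_e`, with
#' `d_a / d_e -> 1/sqrt(2)` for highly unequal sds (the ~30% worst-case
#' underestimate of `d_a`).
#'
#' @param a,b [nd_normal] objects.
#' @return `list(d_a, d_e)`.
#' @export
dprime_approx <- function(a, b) {
  stopifnot(inherits(a, "nd_normal"), inherits(b, "nd_normal"),
            a$k == b$k)
  d_a <- mahal_dist(a$mu, b$mu, (a$Sigma + b$Sigma) / 2)
  S_avg <- (sym_sqrt(a$Sigma) + sym_sqrt(b$Sigma)) / 2
  d_e <- sqrt(sum(solve(S_avg, a$mu - b$mu)^2))
  list(d_a = d_a, d_e = d_e)
}

#' Bayes discriminability index d'_b
#'
#' The separation of two unit-variance normals having the same overlap as
#' the given pair: `d_b = -2 * qnorm(p_e)` where `p_e` is the Bayes error
#' with equal priors and identity outcome values. It reduces to the
#' Mahalanobis distance when the covariances are equal, is symmetric in
#' the two classes, and remains positive for equal means with unequal
#' covariances. When `p_e` underflows double precision (d' above ~75),
#' `d_b` is infinite; for 1d problems the returned index falls back to
#' `d_e` with `fallback = TRUE`.
#'
#' @param a,b [nd_normal] objects.
#' @param method Passed to the two-class error computation (`"gx2"` or
#'   `"ray"`).
#' @param ... Passed to [norm_prob()] when `method = "ray"`.
#' @return `list(d_b, p_e, fallback)`.
#' @export
dprime_bayes <- function(a, b, method = "gx2", ...) {
  stopifnot(inherits(a, "nd_normal"), inherits(b, "nd_normal"),
            a$k == b$k)
  vs <- value_structure(c(0.5, 0.5))
  bnd <- bayes_boundary(a, b, vs)
  ## integrate each error rate directly (a's error on the inverted
  ## boundary) so tiny rates are not lost to 1 - (1 - tiny) underflow
  inv <- quad_domain(-bnd$Q2, -bnd$q1, -bnd$q0)
  pr <- function(cl, dom) {
    if (method == "gx2") quad_prob_gx2(cl, dom)
    else norm_prob(cl, dom, ...)$p
  }
  ## max() keeps tiny error rates (where 1 - p underflows) and resolves
  ## the degenerate identical-class boundary (ties go against class a)
  p_err_a <- max(pr(a, inv), 1 - pr(a, bnd))
  p_e <- (p_err_a + pr(b, bnd)) / 2
  fallback <- FALSE
  if (p_e >= .Machine$double.xmin) {
    d_b <- -2 * stats::qnorm(p_e)
  } else {
    fallback <- TRUE
    d_b <- if (a$k == 1L) dprime_approx(a, b)$d_e else Inf
  }
  list(d_b = d_b, p_e = p_e, fallback = fallback)
}

#' Optimal yes/no error rates for two 1d normals
#'
#' Closed form for the Bayes error rates of a single-interval (yes/no)
#' task between `N(mu_a, sigma_a^2)` and `N(mu_b, sigma_b^2)` with equal
#' priors. For unequal sds the log-likelihood ratio is a scaled and
#' shifted noncentral chi-square with 1 degree of freedom under each
#' class: with `D = sigma_a^2 - sigma_b^2` (labels swapped internally so
#' `sigma_a > sigma_b`), `lambda = ((mu_a - mu_b)/D)^2` and
#' `c = lambda + 2 log(sigma_a/sigma_b)/D`,
#' `p(B|a) = P(chi2'_1(sigma_a^2 lambda) < sigma_b^2 c)` and
#' `p(A|b) = P(chi2'_1(sigma_b^2 lambda) > sigma_a^2 c)`. With equal sds
#' both error rates are `pnorm(-|mu_a - mu_b| / (2 sigma))`.
#'
#' @param mu_a,sigma_a,mu_b,sigma_b 1d class parameters (`sigma > 0`).
#' @return `list(p_b_given_a, p_a_given_b, p_e)`.
#' @examples
#' yes_no_errors(0, 1, 1, 1)$p_e   # pnorm(-1/2)
#' @export
yes_no_errors <- function(mu_a, sigma_a, mu_b, sigma_b) {
  if (sigma_a <= 0 || sigma_b <= 0) stop("sds must be positive")
  if (sigma_a == sigma_b) {
    p <- stats::pnorm(-abs(mu_a - mu_b) / (2 * sigma_a))
    return(list(p_b_given_a = p, p_a_given_b = p, p_e = p))
  }
  swapped <- sigma_a < sigma_b
  if (swapped) {
    tmp <- mu_a; mu_a <- mu_b; mu_b <- tmp
    tmp <- sigma_a; sigma_a <- sigma_b; sigma_b <- tmp
  }
  D <- sigma_a^2 - sigma_b^2
  lam <- ((mu_a - mu_b) / D)^2
  cc <- lam + 2 * log(sigma_a / sigma_b) / D
  p_b_a <- ncchisq1_cdf(sigma_b^2 * cc, sigma_a^2 * lam, lower = TRUE)
  p_a_b <- ncchisq1_cdf(sigma_a^2 * cc, sigma_b^2 * lam, lower = FALSE)
  if (swapped) {
    list(p_b_given_a = p_a_b, p_a_given_b = p_b_a,
         p_e = (p_a_b + p_b_a) / 2)
  } else {
    list(p_b_given_a = p_b_a, p_a_given_b = p_a_b,
         p_e = (p_b_a + p_a_b) / 2)
  }
}

## 2d normals ab and ba for the two-interval construction, plus the
## optimal boundary (sa^2-sb^2)(x1^2-x2^2) + 2(mu_a sb^2 - mu_b sa^2)(x1-x2) > 0
two_interval_parts <- function(mu_a, sigma_a, mu_b, sigma_b) {
  ab <- nd_normal(c(mu_a, mu_b), diag(c(sigma_a^2, sigma_b^2)))
  ba <- nd_normal(c(mu_b, mu_a), diag(c(sigma_b^2, sigma_a^2)))
  D <- sigma_a^2 - sigma_b^2
  g <- 2 * (mu_a * sigma_b^2 - mu_b * sigma_a^2)
  bnd <- quad_domain(diag(c(D, -D)), c(g, -g), 0)
  list(ab = ab, ba = ba, boundary = bnd)
}

#' Optimal two-interval task performance
#'
#' In a two-interval task the observer sees an ordered stimulus pair and
#' reports its order. The optimal rule compares the log-likelihood ratios
#' of the two stimuli (not the stimuli themselves): it is a 2d
#' classification between the block normals `ab = N((mu_a, mu_b),
#' diag(sigma_a^2, sigma_b^2))` and its flipped version `ba`, with the
#' quadratic boundary `(sigma_a^2 - sigma_b^2)(x1^2 - x2^2) +
#' 2(mu_a sigma_b^2 - mu_b sigma_a^2)(x1 - x2) > 0`. With equal sds this
#' reduces to `x1 > x2` and `p_c = pnorm(d'/sqrt(2))`. The error is
#' evaluated through the generalized chi-square of the boundary quadratic
#' (a difference of scaled noncentral chi-squares) or by the 2d ray
#' method.
#'
#' @param a,b 1d [nd_normal] objects (or scalars coercible via
#'   `nd_normal`).
#' @param method `"gx2"` (default) or `"ray"`.
#' @param ... Passed to [norm_prob()] for the ray method.
#' @return Object of class `task_result`: `p_e`, `p_c`, `d_b`, `d_a`,
#'   `d_e` (of the 2d pair), `boundary`, `aux` (per-class gx2 params of
#'   the decision variable).
#' @export
two_interval <- function(a, b, method = c("gx2", "ray"), ...) {
  method <- match.arg(method)
  stopifnot(inherits(a, "nd_normal"), inherits(b, "nd_normal"),
            a$k == 1L, b$k == 1L)
  parts <- two_interval_parts(a$mu, sqrt(a$Sigma[1, 1]),
                              b$mu, sqrt(b$Sigma[1, 1]))
  inv <- quad_domain(-parts$boundary$Q2, -parts$boundary$q1,
                     -parts$boundary$q0)
  pr <- function(cl, dom) {
    if (method == "gx2") quad_prob_gx2(cl, dom)
    else norm_prob(cl, dom, ...)$p
  }
  p_err_ab <- max(pr(parts$ab, inv), 1 - pr(parts$ab, parts$boundary))
  p_err_ba <- pr(parts$ba, parts$boundary)
  p_e <- min(max((p_err_ab + p_err_ba) / 2, 0), 1)
  dp <- dprime_approx(parts$ab, parts$ba)
  fallback <- p_e < .Machine$double.xmin
  d_b <- if (!fallback) -2 * stats::qnorm(p_e) else Inf
  structure(list(p_e = p_e, p_c = 1 - p_e, d_b = d_b, d_a = dp$d_a,
                 d_e = dp$d_e, boundary = parts$boundary,
                 aux = list(ab = gx2_params(parts$ab, parts$boundary),
                            ba = gx2_params(parts$ba, parts$boundary)),
                 d_b_fallback = fallback),
            class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("two-interval task: p_c = %.6g, p_e = %.6g, d'_b = %.4g\n",
              x$p_c, x$p_e, x$d_b))
  invisible(x)
}

#' Maximum m-interval (m-alternative forced choice) accuracy
#'
#' One of `m` stimuli comes from the signal class `a`, the rest from `b`;
#' the optimal observer picks the stimulus with the largest log-likelihood
#' ratio `l` of a versus b. The accuracy is
#' `p_c = integral F_b^(m-1)(l) f_a(l) dl`, where `f_a` and `F_b` are the
#' pdf/cdf of `l` under each class — normals when the sds are equal,
#' scaled noncentral chi-squares otherwise. Decreasing in `m`; equals the
#' two-interval accuracy at `m = 2` and `1/m` for identical classes.
#'
#' @param m Number of intervals (integer >= 2).
#' @param mu_a,sigma_a,mu_b,sigma_b 1d class parameters.
#' @return Scalar accuracy in `[1/m, 1]`.
#' @export
m_interval_accuracy <- function(m, mu_a, sigma_a, mu_b, sigma_b) {
  if (m < 2) stop("m must be >= 2")
  if (sigma_a <= 0 || sigma_b <= 0) stop("sds must be positive")
  a <- nd_normal(mu_a, sigma_a^2)
  b <- nd_normal(mu_b, sigma_b^2)
  lr <- bayes_boundary(a, b)       # log-likelihood ratio quadratic
  pa <- gx2_params(a, lr)
  pb <- gx2_params(b, lr)
  if (gx2_sd(pa) == 0 && gx2_sd(pb) == 0) return(1 / m)   # identical classes
  lo <- min(gx2_inv(1e-12, pa), gx2_inv(1e-12, pb))
  hi <- max(gx2_inv(1 - 1e-12, pa), gx2_inv(1 - 1e-12, pb))
  ## the noncentral-chi-square density of l is unbounded at its offset
  ## point; split the quadrature there so the singularity sits at panel
  ## endpoints, where the adaptive rule handles it well
  splits <- sort(unique(c(lo, pa$m, pb$m, hi)))
  splits <- splits[splits >= lo & splits <= hi]
  val <- 0
  for (j in seq_len(length(splits) - 1L))
    val <- val + stats::integrate(function(l)
      gx2_cdf(l, pb)^(m - 1) * gx2_pdf(l, pa),
      splits[j], splits[j + 1L], rel.tol = 1e-10, abs.tol = 1e-11,
      subdivisions = 1000L)$value
  val
}

#' ROC curve between two classes
#'
#' Sweeps a decision criterion and tracks `(p(false alarm), p(hit))`,
#' where a hit is assigning class `a` to an `a` stimulus. In
#' `"criterion"` mode a scalar criterion is swept across 1d classes
#' (respond `a` when `x > c`); in `"likelihood_ratio"` mode the offset of
#' the Bayes boundary between the two classes (a likelihood-ratio
#' contour) is swept, in any dimension. The area under the
#' likelihood-ratio curve equals the optimal two-interval accuracy, and
#' the point farthest from the diagonal (maximal `hit - fa`) yields the
#' Bayes discriminability estimate `2 * qnorm(accuracy)`.
#'
#' @param a,b [nd_normal] objects, or numeric sample vectors (1d,
#'   criterion mode).
#' @param mode `"likelihood_ratio"` (default) or `"criterion"`.
#' @param n_grid Number of sweep points (spread uniformly in the z-domain
#'   of the criterion).
#' @return Object of class `nint_roc`: data frame `curve` (columns
#'   `crit`, `fa`, `hit`), `auc`, `d_b` (farthest-point estimate),
#'   `best_acc`.
#' @export
roc_curve <- function(a, b, mode = c("likelihood_ratio", "criterion"),
                      n_grid = 501L) {
  mode <- match.arg(mode)
  if (mode == "criterion") {
    if (inherits(a, "nd_normal")) {
      stopifnot(a$k == 1L, b$k == 1L)
      mu <- c(a$mu, b$mu); sd2 <- sqrt(c(a$Sigma[1, 1], b$Sigma[1, 1]))
      zs <- seq(-8, 8, length.out = n_grid)
      crit <- sort(unique(c(mu[1] + zs * sd2[1], mu[2] + zs * sd2[2])))
      hit <- stats::pnorm(crit, mu[1], sd2[1], lower.tail = FALSE)
      fa <- stats::pnorm(crit, mu[2], sd2[2], lower.tail = FALSE)
    } else {
      xa <- as.numeric(a); xb <- as.numeric(b)
      crit <- sort(unique(c(xa, xb)))
      hit <- vapply(crit, function(cc) mean(xa > cc), 0)
      fa <- vapply(crit, function(cc) mean(xb > cc), 0)
    }
  } else {
    stopifnot(inherits(a, "nd_normal"), inherits(b, "nd_normal"))
    bnd <- bayes_boundary(a, b)
    pa <- gx2_params(a, bnd)
    pb <- gx2_params(b, bnd)
    ## sweep the q0 offset (likelihood-ratio criterion) along the
    ## quantiles of the decision variable under both classes, so the
    ## curve is sampled uniformly in probability rather than in raw
    ## criterion units
    probs <- seq(1e-6, 1 - 1e-6, length.out = ceiling(n_grid / 2))
    crit <- sort(unique(c(gx2_inv(probs, pa), gx2_inv(probs, pb))))
    hit <- 1 - gx2_cdf(crit, pa)
    fa <- 1 - gx2_cdf(crit, pb)
  }
  ord <- order(fa, hit)
  fa_s <- c(0, fa[ord], 1); hit_s <- c(0, hit[ord], 1)
  auc <- sum(diff(fa_s) * (hit_s[-1] + hit_s[-length(hit_s)]) / 2)
  i_best <- which.max(hit - fa)
  best_acc <- (hit[i_best] + 1 - fa[i_best]) / 2
  d_b <- 2 * stats::qnorm(best_acc)
  structure(list(curve = data.frame(crit = crit, fa = fa, hit = hit),
                 auc = auc, d_b = d_b, best_acc = best_acc, mode = mode),
            class = "nint_roc")
}

#' @export
print.nint_roc <- function(x, ...) {
  cat(sprintf("ROC curve (%s mode): AUC = %.6g, d'_b at farthest point = %.4g\n",
              x$mode, x$auc, x$d_b))
  invisible(x)
}

#' @export
plot.nint_roc <- function(x, ...) {
  graphics::plot(x$curve$fa, x$curve$hit, type = "l",
                 xlab = "p(false alarm)", ylab = "p(hit)",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
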