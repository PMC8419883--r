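#' Priors and outcome values for classification
#'
#' Bundles class priors with an outcome value matrix `V` whose entry
#' `v_ij` is the value of classifying a sample from class `i` as class
#' `j`. The Bayes classifier uses the relative value gain of each class,
#' `v_i = v_ii - sum_{j != i} v_ij`, which must be positive.
#'
#' @param priors Nonnegative vector summing to 1 (normalized if not).
#' @param V Value matrix; the default (identity) scores correctness only,
#'   in which case the Bayes rule maximizes the posterior.
#' @return Object of class `value_structure` with `priors`, `V`, `v`
#'   (relative gains) and `n_classes`.
#' @export
value_structure <- function(priors, V = NULL) {
  priors <- as.numeric(priors)
  if (any(priors < 0) || sum(priors) <= 0)
    stop("priors must be nonnegative and not all zero")
  priors <- priors / sum(priors)
  nc <- length(priors)
  if (is.null(V)) V <- diag(nc)
  V <- as_matrix(V)
  if (!all(dim(V) == nc)) stop("'V' must be ", nc, " x ", nc)
  if (any(!is.finite(V))) stop("'V' must be finite")
  v <- diag(V) - (rowSums(V) - diag(V))
  structure(list(priors = priors, V = V, v = v, n_classes = nc),
            class = "value_structure")
}

#' Bayes-optimal quadratic boundary between two normals
#'
#' Returns the quadratic `beta(x) > 0 <=> choose the first class`, from
#' the log ratio of expected value gains:
#' `Q2 = (Sigma_b^-1 - Sigma_a^-1)/2`,
#' `q1 = Sigma_a^-1 mu_a - Sigma_b^-1 mu_b`,
#' `q0 = (mu_b' Sigma_b^-1 mu_b - mu_a' Sigma_a^-1 mu_a)/2
#'       + log(|Sigma_b|/|Sigma_a|)/2 + log(p_a v_a / (p_b v_b))`.
#' With equal covariances the quadratic term vanishes and the boundary is
#' flat.
#'
#' @param a,b [nd_normal] objects (the first and second class).
#' @param vs A [value_structure] for the two classes (default: equal
#'   priors, identity values).
#' @return A quadratic `nint_domain`.
#' @export
bayes_boundary <- function(a, b, vs = value_structure(c(0.5, 0.5))) {
  stopifnot(inherits(a, "nd_normal"), inherits(b, "nd_normal"),
            inherits(vs, "value_structure"))
  if (a$k != b$k) stop("dimension mismatch")
  if (vs$n_classes != 2L) stop("'vs' must describe two classes")
  if (any(vs$v <= 0))
    stop("relative value gains must be positive for a Bayes boundary")
  Sa_i <- solve(a$Sigma); Sb_i <- solve(b$Sigma)
  Q2 <- (Sb_i - Sa_i) / 2
  q1 <- drop(Sa_i %*% a$mu - Sb_i %*% b$mu)
  q0 <- drop(crossprod(b$mu, Sb_i %*% b$mu) -
             crossprod(a$mu, Sa_i %*% a$mu)) / 2 +
    (determinant(b$Sigma)$modulus - determinant(a$Sigma)$modulus) / 2 +
    log(vs$priors[1] * vs$v[1] / (vs$priors[2] * vs$v[2]))
  quad_domain(Q2, q1, as.numeric(q0))
}

#' Classify among normal distributions
#'
#' Computes the error matrix `p_mat[i, j] = P(assigned j | true i)` for
#' Bayes-optimal (or custom) classification. For two classes the decision
#' region of the first class is `beta(x) > 0` (or a supplied custom
#' boundary) and each cell is a normal probability computed through the
#' generalized chi-square route (quadratic boundaries) or the ray method;
#' for more than two classes the region of class `j` is the intersection
#' of its pairwise quadratic regions against every other class
#' (min-of-quadratics), integrable only by the ray method.
#'
#' @param classes List of [nd_normal] objects (length >= 2).
#' @param vs A [value_structure]; default equal priors and identity
#'   values.
#' @param boundary Optional custom two-class boundary: a quadratic or any
#'   `nint_domain` with the convention "inside => class 1".
#' @param method `"auto"` (gx2 when the boundary is quadratic, else ray),
#'   `"gx2"`, or `"ray"`.
#' @param ... Passed to [norm_prob()] for ray-method cells.
#' @return Object of class `norm_classification`: `p_mat`, `p_e`
#'   (prior-weighted error), `boundary` (two-class), `boundaries`
#'   (pairwise list, multi-class), and for two classes with identity
#'   values the indices `d_b`, `d_a`, `d_e` (Bayes index computed with
#'   equal priors; `d_b_fallback` flags where `d_b` was replaced by `d_e`
#'   because the Bayes error underflowed).
#' @examples
#' a <- nd_normal(0, 1); b <- nd_normal(1, 1)
#' classify_normals(list(a, b))$p_mat   # off-diagonals pnorm(-1/2)
#' @export
classify_normals <- function(classes, vs = NULL, boundary = NULL,
                             method = c("auto", "gx2", "ray"), ...) {
  method <- match.arg(method)
  stopifnot(is.list(classes), length(classes) >= 2L)
  lapply(classes, function(x) stopifnot(inherits(x, "nd_normal")))
  nc <- length(classes)
  if (is.null(vs)) vs <- value_structure(rep(1 / nc, nc))
  stopifnot(inherits(vs, "value_structure"))
  if (vs$n_classes != nc) stop("'vs' does not match the number of classes")
  if (!is.null(boundary) && nc != 2L)
    stop("a custom boundary is supported only for two classes")

  if (nc == 2L) {
    bnd <- if (is.null(boundary)) bayes_boundary(classes[[1]], classes[[2]], vs)
           else boundary
    use_gx2 <- switch(method,
                      auto = inherits(bnd, "nint_domain") &&
                             bnd$type == "quadratic",
                      gx2 = TRUE, ray = FALSE)
    if (use_gx2 && (!inherits(bnd, "nint_domain") || bnd$type != "quadratic"))
      stop("method 'gx2' requires a quadratic boundary")
    p_in <- vapply(classes, function(cl) {
      if (use_gx2) quad_prob_gx2(cl, bnd)
      else norm_prob(cl, bnd, ...)$p
    }, 0)
    p_mat <- rbind(c(p_in[1], 1 - p_in[1]),
                   c(p_in[2], 1 - p_in[2]))
    boundaries <- NULL
  } else {
    if (method == "gx2")
      stop("more than two classes requires the ray method ",
           "(min-of-quadratics regions are not quadratic)")
    boundaries <- vector("list", nc)
    for (j in seq_len(nc)) {
      regions <- lapply(setdiff(seq_len(nc), j), function(l) {
        vs2 <- value_structure(c(1, 1) / 2)
        b <- bayes_boundary(classes[[j]], classes[[l]], vs2)
        ## priors/values enter through the offset term
        b$q0 <- b$q0 + log(vs$priors[j] * vs$v[j] /
                             (vs$priors[l] * vs$v[l]))
        b
      })
      boundaries[[j]] <- domain_intersect(regions)
    }
    p_mat <- matrix(0, nc, nc)
    for (i in seq_len(nc)) for (j in seq_len(nc))
      p_mat[i, j] <- norm_prob(classes[[i]], boundaries[[j]], ...)$p
    bnd <- NULL
  }

  rownames(p_mat) <- colnames(p_mat) <-
    if (nc == 2L) c("a", "b") else paste0("c", seq_len(nc))
  p_e <- sum(vs$priors * (1 - diag(p_mat)))
  out <- list(p_mat = p_mat, p_e = p_e, priors = vs$priors, vs = vs,
              boundary = bnd, boundaries = boundaries, n_classes = nc)

  if (nc == 2L && all(vs$V == diag(2))) {
    dp <- dprime_approx(classes[[1]], classes[[2]])
    db <- dprime_bayes(classes[[1]], classes[[2]],
                       method = if (method == "ray") "ray" else "gx2", ...)
    out$d_a <- dp$d_a; out$d_e <- dp$d_e
    out$d_b <- db$d_b; out$d_b_fallback <- db$fallback
  }
  structure(out, class = "norm_classification")
}

#' @export
print.norm_classification <- function(x, ...) {
  cat(sprintf("classification among %d normals\n", x$n_classes))
  cat("error matrix p(assigned | true):\n")
  print(round(x$p_mat, 6))
  cat(sprintf("prior-weighted error p_e = %.6g\n", x$p_e))
  if (!is.null(x$d_b))
    cat(sprintf("d'_b = %.4g%s   d'_a = %.4g   d'_e = %.4g\n", x$d_b,
                if (isTRUE(x$d_b_fallback)) " (fallback)" else "",
                x$d_a, x$d_e))
  invisible(x)
}

#' Maximum-likelihood normal fits from labeled samples
#'
#' Fits one normal per class (sample mean; covariance normalized by the
#' class count `n`, the maximum-likelihood estimate) and priors equal to
#' the relative class frequencies.
#'
#' @param x Numeric matrix or data frame of features (rows =
#'   observations).
#' @param labels Vector of class labels (length `nrow(x)`).
#' @return `list(classes = list of nd_normal, vs = value_structure,
#'   levels = class labels)`.
#' @export
fit_normals <- function(x, labels) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.factor(labels)
  if (nrow(x) != length(labels)) stop("labels do not match rows of x")
  lev <- levels(labels)
  if (length(lev) < 2L) stop("need at least two classes")
  classes <- lapply(lev, function(l) {
    xi <- x[labels == l, , drop = FALSE]
    n <- nrow(xi)
    if (n < 2L) stop("class '", l, "' has fewer than two observations")
    mu <- colMeans(xi)
    Sg <- crossprod(sweep(xi, 2L, mu)) / n
    ev <- eigen((Sg + t(Sg)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(ev, 1))
      stop("class '", l, "' has a singular sample covariance")
    nd_normal(mu, Sg)
  })
  list(classes = classes,
       vs = value_structure(as.numeric(table(labels)) / length(labels)),
       levels = lev)
}

## classify points by a two-class boundary: TRUE = first class.
## Points exactly on the boundary go to the second class.
boundary_assign <- function(boundary, x) {
  stopifnot(inherits(boundary, "nint_domain"))
  if (boundary$type == "quadratic") quad_eval(boundary, x) > 0
  else domain_eval(boundary, x) > 0
}

## expected outcome value of a two-class boundary on labeled samples,
## prior- and value-weighted (priors/values from vs; per-class rates)
sample_value <- function(boundary, x, labels, vs) {
  lev <- levels(as.factor(labels))
  first <- boundary_assign(boundary, x)
  val <- 0
  for (i in 1:2) {
    sel <- labels == lev[i]
    p_first <- mean(first[sel])
    val <- val + vs$priors[i] *
      (p_first * vs$V[i, 1] + (1 - p_first) * vs$V[i, 2])
  }
  val
}

## sample error matrix of a two-class boundary
sample_error_matrix <- function(boundary, x, labels) {
  lev <- levels(as.factor(labels))
  first <- boundary_assign(boundary, x)
  p_mat <- t(vapply(lev, function(l) {
    sel <- labels == l
    c(mean(first[sel]), 1 - mean(first[sel]))
  }, c(0, 0)))
  dimnames(p_mat) <- list(lev, lev)
  p_mat
}

#' Optimize a quadratic boundary on labeled samples
#'
#' Maximizes the prior- and value-weighted expected outcome of classifying
#' the given samples over the `(k+1)(k+2)/2` free parameters of a
#' quadratic boundary, starting from `init` (typically the Bayes boundary
#' of the fitted normals, or a custom boundary, possibly zero-padded from
#' a lower-dimensional feature space). The sample value is piecewise
#' constant in the coefficients, so a derivative-free Nelder--Mead search
#' is used with the coefficient vector scaled to unit norm to remove the
#' scale degeneracy.
#'
#' @param x Feature matrix; `labels` a two-level label vector.
#' @param labels Class labels (first level = "inside" class).
#' @param init Initial quadratic boundary.
#' @param vs A [value_structure] (default: sample frequencies as priors,
#'   identity values).
#' @param maxit Maximum function evaluations.
#' @return A quadratic `nint_domain` with attributes `value` (achieved
#'   sample value), `init_value`, and `converged`.
#' @export
optimize_boundary <- function(x, labels, init, vs = NULL, maxit = 1e4) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("boundary optimization needs two classes")
  stopifnot(inherits(init, "nint_domain"), init$type == "quadratic")
  k <- init$k
  if (ncol(x) != k) stop("dimension mismatch between samples and boundary")
  if (is.null(vs))
    vs <- value_structure(as.numeric(table(labels)) / length(labels))
  ut <- upper.tri(matrix(0, k, k), diag = TRUE)
  pack <- function(q) c(q$Q2[ut], q$q1, q$q0)
  unpack <- function(th) {
    Q2 <- matrix(0, k, k)
    Q2[ut] <- th[seq_len(sum(ut))]
    Q2 <- Q2 + t(Q2) - diag(diag(Q2), k)
    quad_domain(Q2, th[sum(ut) + seq_len(k)], th[length(th)])
  }
  th0 <- pack(init)
  nrm <- sqrt(sum(th0^2))
  if (nrm == 0) stop("initial boundary is identically zero")
  th0 <- th0 / nrm
  obj <- function(th) {
    th <- th / max(sqrt(sum(th^2)), 1e-12)
    -sample_value(unpack(th), x, labels, vs)
  }
  opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12))
  init_val <- sample_value(init, x, labels, vs)
  best <- unpack(opt$par / sqrt(sum(opt$par^2)))
  best_val <- -opt$value
  if (best_val < init_val) {        # optimizer failed to improve: keep init
    best <- init
    best_val <- init_val
    attr(best, "converged") <- FALSE
  } else attr(best, "converged") <- TRUE
  attr(best, "value") <- best_val
  attr(best, "init_value") <- init_val
  best
}

#' Map points or a normal through a boundary's decision variable
#'
#' A two-class quadratic boundary `beta` defines the scalar decision
#' variable `beta(x)` with the criterion at 0. Classifying the mapped
#' scalars against 0 reproduces the multidimensional classification
#' exactly. For a normal class the mapped distribution is the generalized
#' chi-square of the quadratic form.
#'
#' @param object A numeric matrix of points or an [nd_normal].
#' @param boundary A quadratic `nint_domain`.
#' @return A numeric vector of decision-variable values, or a
#'   `gx2_params` object.
#' @export
decision_variable <- function(object, boundary) {
  stopifnot(inherits(boundary, "nint_domain"), boundary$type == "quadratic")
  if (inherits(object, "nd_normal")) return(gx2_params(object, boundary))
  x <- as.matrix(object)
  if (ncol(x) != boundary$k) stop("dimension mismatch")
  quad_eval(boundary, x)
}

#' Project a normal onto an axis
#'
#' Returns the 1d normal of `w' x` for a unit vector `w`:
#' `N(w' mu, w' Sigma w)`.
#'
#' @param normal An [nd_normal].
#' @param w Direction vector (normalized internally).
#' @return A 1d [nd_normal].
#' @export
project_normal <- function(normal, w) {
  stopifnot(inherits(normal, "nd_normal"))
  w <- as.numeric(w)
  if (length(w) != normal$k) stop("dimension mismatch")
  w <- w / sqrt(sum(w^2))
  nd_normal(sum(w * normal$mu),
            drop(crossprod(w, normal$Sigma %*% w)))
}
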