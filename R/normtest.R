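#' Boundary families for testing a normal model
#'
#' A classification experiment with limited trials cannot distinguish a
#' normal model from the true distributions at a single (near-optimal)
#' boundary, so the boundary is swept across the space into regions of
#' error and outcome counts are compared along the sweep. Three common
#' suboptimal families are provided:
#'
#' * `"lr_offset"` (two classes): shifts the constant offset `q0` of the
#'   Bayes boundary, i.e. moves along contours of the log likelihood
#'   ratio. Both a biased criterion and a mis-scaled internal
#'   discriminability correspond to such a shift.
#' * `"cov_scale"`: rebuilds the Bayes boundaries from covariance
#'   matrices multiplied by each scale factor (an observer whose internal
#'   discriminability differs from the true one).
#' * `"prior_sweep"`: rebuilds the boundaries under each assumed prior
#'   for the first class (multi-class supported; the remaining priors are
#'   scaled proportionally).
#'
#' The family contains the optimal boundary at its reference parameter
#' (offset 0, scale 1, the true prior).
#'
#' @param classes List of [nd_normal] objects.
#' @param vs A [value_structure].
#' @param kind One of `"lr_offset"`, `"cov_scale"`, `"prior_sweep"`.
#' @param grid Numeric vector of family parameters (offsets, scale
#'   factors, or assumed priors of the first class).
#' @return Object of class `boundary_family`; each member records the
#'   (possibly modified) classes and value structure that generate its
#'   decision regions, plus the two-class quadratic where applicable.
#' @export
make_family <- function(classes, vs, kind = c("lr_offset", "cov_scale",
                                              "prior_sweep"),
                        grid) {
  kind <- match.arg(kind)
  nc <- length(classes)
  stopifnot(nc >= 2L, inherits(vs, "value_structure"),
            vs$n_classes == nc, length(grid) >= 1L)
  if (kind == "lr_offset" && nc != 2L)
    stop("'lr_offset' sweeps are defined for two classes")
  members <- lapply(grid, function(g) {
    if (kind == "lr_offset") {
      b <- bayes_boundary(classes[[1]], classes[[2]], vs)
      b$q0 <- b$q0 + g
      list(boundary = b, classes = classes, vs = vs, offset = g)
    } else if (kind == "cov_scale") {
      if (g <= 0) stop("covariance scales must be positive")
      scaled <- lapply(classes, function(cl) nd_normal(cl$mu, cl$Sigma * g))
      list(boundary = if (nc == 2L)
             bayes_boundary(scaled[[1]], scaled[[2]], vs) else NULL,
           classes = scaled, vs = vs, offset = 0)
    } else {
      if (g <= 0 || g >= 1) stop("assumed priors must be inside (0, 1)")
      pr <- vs$priors
      pr_new <- pr * (1 - g) / sum(pr[-1L])
      pr_new[1L] <- g
      vs2 <- value_structure(pr_new, vs$V)
      list(boundary = if (nc == 2L)
             bayes_boundary(classes[[1]], classes[[2]], vs2) else NULL,
           classes = classes, vs = vs2, offset = 0)
    }
  })
  structure(list(kind = kind, grid = grid, members = members,
                 classes = classes, vs = vs, n_classes = nc),
            class = "boundary_family")
}

## log expected value gain of deciding class j for sample rows x, under
## the member's classes/priors; the argmax over j is the decision rule
member_assign <- function(member, x, nc) {
  if (nc == 2L && !is.null(member$boundary))
    return(ifelse(boundary_assign(member$boundary, x), 1L, 2L))
  scores <- vapply(seq_len(nc), function(j) {
    cl <- member$classes[[j]]
    Si <- solve(cl$Sigma)
    d <- sweep(x, 2L, cl$mu)
    -rowSums((d %*% Si) * d) / 2 -
      as.numeric(determinant(cl$Sigma)$modulus) / 2 +
      log(member$vs$priors[j] * member$vs$v[j])
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) scores <- matrix(scores, 1L)
  max.col(scores, ties.method = "last")
}

## analytic error matrix of a family member under the *model* normals
member_model_rates <- function(member, model_classes, nc, ...) {
  p <- matrix(0, nc, nc)
  if (nc == 2L && !is.null(member$boundary)) {
    for (i in 1:2) {
      p1 <- quad_prob_gx2(model_classes[[i]], member$boundary)
      p[i, ] <- c(p1, 1 - p1)
    }
  } else {
    regions <- multiclass_regions(member$classes, member$vs)
    for (i in seq_len(nc)) for (j in seq_len(nc))
      p[i, j] <- norm_prob(model_classes[[i]], regions[[j]], ...)$p
  }
  p
}

## per-class decision regions (intersections of pairwise quadratics)
multiclass_regions <- function(classes, vs) {
  nc <- length(classes)
  lapply(seq_len(nc), function(j) {
    regions <- lapply(setdiff(seq_len(nc), j), function(l) {
      b <- bayes_boundary(classes[[j]], classes[[l]],
                          value_structure(c(0.5, 0.5)))
      b$q0 <- b$q0 + log(vs$priors[j] * vs$v[j] /
                           (vs$priors[l] * vs$v[l]))
      b
    })
    domain_intersect(regions)
  })
}

#' Outcome count bands along a boundary family
#'
#' For every boundary in a family, computes each outcome rate (every
#' error-matrix cell and the prior-weighted overall error) twice: under
#' the fitted normal model (analytically) and under the true source (by
#' classifying the supplied labeled samples, with a nonparametric
#' bootstrap for the sampling uncertainty of the observed rate). Each
#' rate is reported with the binomial sd of the corresponding count
#' fraction at `n_trials` trials — the count of any single outcome is
#' binomial, and with several classes the per-class response counts are
#' multinomial, making the total error count binomial again — so the two
#' bands can be overlaid to judge whether the normal model predicts the
#' countable outcomes of an experiment of that size.
#'
#' @param x Feature matrix of true-source samples.
#' @param labels Class labels (levels matched to `family$classes` in
#'   order).
#' @param family A [make_family()] object.
#' @param model Optional list of [nd_normal] objects to use as the normal
#'   model (default: the family's classes).
#' @param n_trials Number of experimental trials per class setting the
#'   binomial band width.
#' @param n_boot Bootstrap resamples for the observed-rate sd.
#' @param seed Optional integer seed for the bootstrap.
#' @param ... Passed to [norm_prob()] for multi-class model cells.
#' @return A data frame with one row per (family parameter, outcome,
#'   source): columns `param`, `outcome` (`"i:j"` cells or `"error"`),
#'   `source` (`"model"` or `"observed"`), `mean`, `sd`.
#' @export
outcome_bands <- function(x, labels, family, model = NULL,
                          n_trials = 100L, n_boot = 1000L, seed = NULL,
                          ...) {
  stopifnot(inherits(family, "boundary_family"), n_trials >= 1L)
  x <- as.matrix(x); storage.mode(x) <- "double"
  labels <- as.factor(labels)
  nc <- family$n_classes
  if (nlevels(labels) != nc)
    stop("labels must have exactly ", nc, " levels (one per class)")
  lev <- levels(labels)
  if (is.null(model)) model <- family$classes
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  priors <- family$vs$priors
  binom_sd <- function(p) sqrt(pmax(p * (1 - p), 0) / n_trials)
  rows <- list()
  add_row <- function(param, outcome, source, mean, sd)
    rows[[length(rows) + 1L]] <<- data.frame(
      param = param, outcome = outcome, source = source,
      mean = mean, sd = sd, stringsAsFactors = FALSE)
  for (gi in seq_along(family$grid)) {
    member <- family$members[[gi]]
    p_model <- member_model_rates(member, model, nc, ...)
    p_obs <- matrix(0, nc, nc)
    p_boot_sd <- matrix(0, nc, nc)
    for (i in seq_len(nc)) {
      xi <- x[labels == lev[i], , drop = FALSE]
      asg <- member_assign(member, xi, nc)
      p_obs[i, ] <- tabulate(asg, nbins = nc) / nrow(xi)
      bs <- matrix(0, n_boot, nc)
      for (bb in seq_len(n_boot)) {
        idx <- sample.int(nrow(xi), replace = TRUE)
        bs[bb, ] <- tabulate(asg[idx], nbins = nc) / nrow(xi)
      }
      p_boot_sd[i, ] <- apply(bs, 2L, stats::sd)
    }
    g <- family$grid[gi]
    for (i in seq_len(nc)) for (j in seq_len(nc)) {
      oc <- paste0(lev[i], ":", lev[j])
      add_row(g, oc, "model", p_model[i, j], binom_sd(p_model[i, j]))
      add_row(g, oc, "observed", p_obs[i, j],
              sqrt(binom_sd(p_obs[i, j])^2 + p_boot_sd[i, j]^2))
    }
    add_row(g, "error", "model", sum(priors * (1 - diag(p_model))),
            sqrt(sum(priors^2 * binom_sd(diag(p_model))^2)))
    add_row(g, "error", "observed", sum(priors * (1 - diag(p_obs))),
            sqrt(sum(priors^2 * (binom_sd(diag(p_obs))^2 +
                                   diag(p_boot_sd)^2))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
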