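#' Standard normal distribution along a ray
#'
#' A standard k-dimensional normal restricted to a double ray (a full line
#' through the origin) has radial distribution given by the chi
#' distribution, symmetrically extended to negative distances:
#' `ray_cdf(z, k) = (1 + sign(z) * F_chi2_k(z^2)) / 2` and
#' `ray_pdf(z, k) = |z| * f_chi2_k(z^2)`. For `k = 1` the density is the
#' standard normal density; in higher dimensions it rises then falls
#' outward as the solid-angle volume grows.
#'
#' @param z Signed distance(s) along the ray, in whitened sd units.
#' @param k Dimension (integer >= 1).
#' @return Probabilities/densities, vectorized over `z`.
#' @examples
#' ray_pdf(1, 1) == dnorm(1)
#' ray_cdf(0, 5)  # 0.5 in any dimension
#' @export
ray_cdf <- function(z, k) {
  if (k < 1) stop("k must be >= 1")
  (1 + sign(z) * stats::pchisq(z^2, df = k)) / 2
}

#' @rdname ray_cdf
#' @export
ray_pdf <- function(z, k) {
  if (k < 1) stop("k must be >= 1")
  out <- abs(z) * stats::dchisq(z^2, df = k)
  ## k = 1: dchisq is infinite at 0 but |z| * f(z^2) -> dnorm(0)
  if (any(z == 0)) out[z == 0] <- if (k == 1) stats::dnorm(0) else 0
  out
}

## complementary ray cdf with accurate upper tail
ray_ccdf <- function(z, k) {
  ifelse(z > 0,
         stats::pchisq(z^2, df = k, lower.tail = FALSE) / 2,
         (1 + stats::pchisq(z^2, df = k)) / 2)
}

#' Probability content of a ray through a domain
#'
#' Given the trace of a domain along a double ray (initial sign `psi` and
#' sorted crossings `z_i`) and the dimension `k`, returns
#' `alpha = psi + 1 + 2 psi sum_i (-1)^i ray_ccdf(z_i)`, the domain's
#' probability on the ray as a fraction of `1/Omega_k` (so `alpha` lies in
#' `[0, 2]`; 2 means the whole double ray is inside the domain).
#'
#' @param trace `list(psi, roots)` as returned by [trace_ray()].
#' @param k Dimension.
#' @return Scalar in `[0, 2]`.
#' @export
slice_alpha <- function(trace, k) {
  psi <- trace$psi
  r <- trace$roots
  a <- psi + 1
  if (length(r))
    a <- a + 2 * psi * sum((-1)^seq_along(r) * ray_ccdf(r, k))
  min(max(a, 0), 2)
}

## ---------------------------------------------------------------------------
## Batched tracing: evaluate alpha for many whitened directions at once,
## calling the (vectorized) domain function on large point blocks. This is
## what makes grid and Monte-Carlo integration fast in R.

## alpha for a batch of rays through a whitened quadratic.
## dirs: n x k unit directions. Returns list(alpha, roots = data frame
## (ray, z)).
batch_alpha_quad <- function(qt, dirs, k) {
  a <- rowSums((dirs %*% qt$Q2) * dirs)
  b <- drop(dirs %*% qt$q1)
  c0 <- qt$q0
  n <- nrow(dirs)
  scale <- pmax(abs(a), abs(b), abs(c0), 1e-300)
  tolc <- 1e-14 * scale
  psi <- integer(n)
  r1 <- rep(NA_real_, n); r2 <- rep(NA_real_, n)
  quad <- abs(a) > tolc
  lin <- !quad & (abs(b) > tolc)
  flat <- !quad & !lin
  psi[quad] <- sign(a[quad])
  psi[lin] <- -sign(b[lin])
  psi[flat] <- sign(c0)
  if (any(lin)) r1[lin] <- -c0 / b[lin]
  if (any(quad)) {
    disc <- b^2 - 4 * a * c0
    has <- quad & disc > 0
    if (any(has)) {
      sq <- sqrt(disc[has])
      bb <- b[has]
      s <- -(bb + ifelse(bb >= 0, 1, -1) * sq) / 2
      ra <- s / a[has]
      rb <- ifelse(abs(s) > 0, c0 / s, -bb / (2 * a[has]))
      r1[has] <- pmin(ra, rb)
      r2[has] <- pmax(ra, rb)
    }
  }
  alpha <- psi + 1 +
    2 * psi * (-ifelse(is.na(r1), 0, ray_ccdf(r1, k)) +
                 ifelse(is.na(r2), 0, ray_ccdf(r2, k)))
  alpha <- pmin(pmax(alpha, 0), 2)
  roots <- data.frame(ray = c(which(!is.na(r1)), which(!is.na(r2))),
                      z = c(r1[!is.na(r1)], r2[!is.na(r2)]))
  list(alpha = alpha, roots = roots)
}

## alpha for a batch of rays through a whitened implicit field f(z).
## f takes an N x k matrix. Chunked so point blocks stay below ~2e6 rows.
batch_alpha_implicit <- function(f, dirs, k, m, n_scan,
                                 z_tol = 1e-10, chunk_rows = 2e6) {
  n <- nrow(dirs)
  zg <- seq(-m, m, length.out = n_scan + 1L)
  zg[1L] <- -m * (1 - 1e-9); zg[length(zg)] <- m * (1 - 1e-9)
  nz <- length(zg)
  per <- max(1L, floor(chunk_rows / nz))
  alpha <- numeric(n)
  root_ray <- list(); root_z <- list()
  for (start in seq(1L, n, by = per)) {
    idx <- start:min(start + per - 1L, n)
    nd <- length(idx)
    ## points: for each ray (outer) and z (inner)
    pts <- dirs[rep(idx, each = nz), , drop = FALSE] * rep(zg, nd)
    fv <- f(pts)
    if (length(fv) != nd * nz || any(!is.finite(fv)))
      stop("implicit domain function returned non-finite or wrongly ",
           "shaped values during ray tracing")
    fm <- matrix(fv, nrow = nz)              # column = one ray
    s <- sign(fm)
    ## nudge exact zeros to a neighbouring sign
    if (any(s == 0)) {
      for (col in which(colSums(s == 0) > 0)) {
        sc <- s[, col]
        for (i in which(sc == 0))
          sc[i] <- if (i > 1L) sc[i - 1L] else sc[min(i + 1L, nz)]
        s[, col] <- sc
      }
    }
    flips <- which(s[-1L, , drop = FALSE] * s[-nz, , drop = FALSE] < 0,
                   arr.ind = TRUE)
    psi <- s[1L, ]
    if (nrow(flips)) {
      lo <- zg[flips[, 1L]]; hi <- zg[flips[, 1L] + 1L]
      ray_of <- flips[, 2L]
      flo <- fm[flips]
      it <- ceiling(log2((2 * m / n_scan) / z_tol)) + 2L
      for (step in seq_len(max(it, 1L))) {
        mid <- (lo + hi) / 2
        fmid <- f(dirs[idx[ray_of], , drop = FALSE] * mid)
        left <- flo * fmid > 0
        lo[left] <- mid[left]; flo[left] <- fmid[left]
        hi[!left] <- mid[!left]
        if (max(hi - lo) < z_tol) break
      }
      z <- (lo + hi) / 2
      ## per-ray alternating signs in order of increasing z
      ord <- order(ray_of, z)
      z <- z[ord]; ray_of <- ray_of[ord]
      pos <- stats::ave(z, ray_of, FUN = seq_along)
      contrib <- 2 * psi[ray_of] * (-1)^pos * ray_ccdf(z, k)
      sums <- rowsum(contrib, ray_of)
      aidx <- as.integer(rownames(sums))
      alpha_chunk <- psi + 1
      alpha_chunk[aidx] <- alpha_chunk[aidx] + sums[, 1L]
      root_ray[[length(root_ray) + 1L]] <- idx[ray_of]
      root_z[[length(root_z) + 1L]] <- z
    } else alpha_chunk <- psi + 1
    alpha[idx] <- pmin(pmax(alpha_chunk, 0), 2)
  }
  list(alpha = alpha,
       roots = data.frame(ray = unlist(root_ray) %||% integer(0),
                          z = unlist(root_z) %||% numeric(0)))
}

## alpha for explicit (callable ray-trace) domains: per-ray loop.
batch_alpha_explicit <- function(domain, S, mu, dirs, k) {
  n <- nrow(dirs)
  alpha <- numeric(n)
  root_ray <- list(); root_z <- list()
  for (i in seq_len(n)) {
    Sn <- drop(S %*% dirs[i, ])
    len <- sqrt(sum(Sn^2))
    tr <- trace_ray(domain, mu, Sn / len)
    tr$roots <- tr$roots / len
    alpha[i] <- slice_alpha(tr, k)
    if (length(tr$roots)) {
      root_ray[[length(root_ray) + 1L]] <- rep(i, length(tr$roots))
      root_z[[length(root_z) + 1L]] <- tr$roots
    }
  }
  list(alpha = alpha,
       roots = data.frame(ray = unlist(root_ray) %||% integer(0),
                          z = unlist(root_z) %||% numeric(0)))
}

## batched alpha dispatcher in whitened space
make_batch_alpha <- function(normal, domain) {
  S <- sym_sqrt(normal$Sigma)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) stop("singular covariance")
  mu <- normal$mu
  k <- normal$k
  if (domain$type == "quadratic") {
    qt <- standardize_quadratic(domain, normal)
    function(dirs) batch_alpha_quad(qt, dirs, k)
  } else if (domain$type == "implicit") {
    f <- domain$f
    fw <- function(z) f(sweep(z %*% S, 2L, mu, "+"))
    function(dirs) batch_alpha_implicit(fw, dirs, k, domain$m,
                                        domain$n_scan)
  } else {
    function(dirs) batch_alpha_explicit(domain, S, mu, dirs, k)
  }
}

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  bsub <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- bsub
  J[cbind(i + 1L, i)] <- bsub
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1L, ]^2)
}

## Adaptive angular integration of alpha over half the angular space.
##
## 2d: panels over theta in [0, pi]; 3d: rectangles in (u = cos(theta),
## phi) over [-1,1] x [0, pi] (the sin(theta) area element is absorbed by
## u). Every panel carries two nested Gauss-Legendre estimates (16 vs 8
## points in 2d, 8x8 vs 4x4 in 3d); their difference is the panel error
## estimate. Panels with the largest errors are split (2-way in 2d, 4-way
## in 3d) in batches until the summed error estimate meets the tolerance
## or the ray budget is reached. alpha is piecewise smooth with
## square-root behaviour where domain boundaries become tangent to rays,
## so local refinement concentrates exactly along those angular curves.
adaptive_angular <- function(batch, k, tol, max_nodes = 3e5,
                             init_div = NULL, min_depth = 2L,
                             safety = 1) {
  if (k == 2) {
    gh <- gauss_legendre(16L); glo <- gauss_legendre(8L)
    nodes1 <- c(gh$nodes, glo$nodes)
    wh <- gh$weights; wl <- glo$weights
    n_hi <- 16L; n_all <- 24L; n_child <- 2L
    total_width <- pi
    make_dirs <- function(lo, hi) {
      mid <- (lo + hi) / 2; half <- (hi - lo) / 2
      th <- rep(mid, each = n_all) + rep(half, each = n_all) * nodes1
      cbind(cos(th), sin(th))
    }
    panel_width <- function(lo, hi) hi - lo
    split_panel <- function(lo, hi) {
      mid <- (lo + hi) / 2
      list(lo = c(lo, mid), hi = c(mid, hi))
    }
    nd0 <- init_div %||% 32L
    edges0 <- seq(0, pi, length.out = nd0 + 1L)
    init <- list(lo = edges0[-(nd0 + 1L)], hi = edges0[-1L])
  } else {
    gh <- gauss_legendre(8L); glo <- gauss_legendre(4L)
    ## per-panel node layout: 64 high nodes then 16 low nodes, as (u, phi)
    uh_n <- rep(gh$nodes, times = 8L); ph_n <- rep(gh$nodes, each = 8L)
    whh <- rep(gh$weights, times = 8L) * rep(gh$weights, each = 8L)
    ul_n <- rep(glo$nodes, times = 4L); pl_n <- rep(glo$nodes, each = 4L)
    wll <- rep(glo$weights, times = 4L) * rep(glo$weights, each = 4L)
    un <- c(uh_n, ul_n); pn <- c(ph_n, pl_n)
    n_hi <- 64L; n_all <- 80L; n_child <- 4L
    total_width <- 2 * pi
    make_dirs <- function(lo, hi) {
      um <- (lo[, 1] + hi[, 1]) / 2; uw <- (hi[, 1] - lo[, 1]) / 2
      pm <- (lo[, 2] + hi[, 2]) / 2; pw <- (hi[, 2] - lo[, 2]) / 2
      uu <- rep(um, each = n_all) + rep(uw, each = n_all) * un
      pp <- rep(pm, each = n_all) + rep(pw, each = n_all) * pn
      st <- sqrt(pmax(1 - uu^2, 0))
      cbind(st * cos(pp), st * sin(pp), uu)
    }
    panel_width <- function(lo, hi) (hi[, 1] - lo[, 1]) * (hi[, 2] - lo[, 2])
    split_panel <- function(lo, hi) {
      um <- (lo[, 1] + hi[, 1]) / 2; pm <- (lo[, 2] + hi[, 2]) / 2
      list(lo = rbind(cbind(lo[, 1], lo[, 2]), cbind(um, lo[, 2]),
                      cbind(lo[, 1], pm), cbind(um, pm)),
           hi = rbind(cbind(um, pm), cbind(hi[, 1], pm),
                      cbind(um, hi[, 2]), cbind(hi[, 1], hi[, 2])))
    }
    nd0 <- init_div %||% 12L
    g0 <- expand.grid(u = seq_len(nd0), p = seq_len(nd0))
    ue <- seq(-1, 1, length.out = nd0 + 1L)
    pe <- seq(0, pi, length.out = nd0 + 1L)
    init <- list(lo = cbind(ue[g0$u], pe[g0$p]),
                 hi = cbind(ue[g0$u + 1L], pe[g0$p + 1L]))
  }

  all_dirs <- list(); all_roots <- list(); rays_so_far <- 0L

  eval_panels <- function(lo, hi) {
    np <- if (k == 2) length(lo) else nrow(lo)
    dirs <- make_dirs(lo, hi)
    res <- batch(dirs)
    if (nrow(res$roots)) {
      res$roots$ray <- res$roots$ray + rays_so_far
      all_roots[[length(all_roots) + 1L]] <<- res$roots
    }
    all_dirs[[length(all_dirs) + 1L]] <<- dirs
    rays_so_far <<- rays_so_far + nrow(dirs)
    am <- matrix(res$alpha, nrow = n_all)
    wdt <- panel_width(lo, hi)
    if (k == 2) {
      v_hi <- colSums(am[seq_len(n_hi), , drop = FALSE] * wh) * wdt / 2
      v_lo <- colSums(am[-seq_len(n_hi), , drop = FALSE] * wl) * wdt / 2
    } else {
      v_hi <- colSums(am[seq_len(n_hi), , drop = FALSE] * whh) * wdt / 4
      v_lo <- colSums(am[-seq_len(n_hi), , drop = FALSE] * wll) * wdt / 4
    }
    list(val = v_hi, err = abs(v_hi - v_lo))
  }

  tol_int <- tol * 2 * total_width * safety
  leaves <- init
  ev <- eval_panels(init$lo, init$hi)
  val <- ev$val; err <- ev$err
  depth <- rep(0L, length(val))
  repeat {
    shallow <- depth < min_depth
    tot_err <- sum(err)
    if ((tot_err < tol_int && !any(shallow)) ||
        rays_so_far + n_all * n_child > max_nodes)
      break
    ## split the leading error carriers plus panels below the forced
    ## minimum depth (guards against quadrature nodes missing a small
    ## angular island of the domain entirely)
    thr <- max(err) / 4
    sel <- which(err >= max(thr, tol_int / (4 * length(err))) | shallow)
    if (!length(sel)) break
    if (length(sel) > 256L) sel <- sel[order(err[sel],
                                             decreasing = TRUE)[1:256]]
    room <- floor((max_nodes - rays_so_far) / (n_all * n_child))
    if (length(sel) > room) {
      if (room < 1L) break
      sel <- sel[order(err[sel], decreasing = TRUE)[seq_len(room)]]
    }
    if (k == 2) {
      ch <- split_panel(leaves$lo[sel], leaves$hi[sel])
      leaves$lo <- leaves$lo[-sel]; leaves$hi <- leaves$hi[-sel]
    } else {
      ch <- split_panel(leaves$lo[sel, , drop = FALSE],
                        leaves$hi[sel, , drop = FALSE])
      leaves$lo <- leaves$lo[-sel, , drop = FALSE]
      leaves$hi <- leaves$hi[-sel, , drop = FALSE]
    }
    child_depth <- rep(depth[sel] + 1L, times = n_child)
    val <- val[-sel]; err <- err[-sel]; depth <- depth[-sel]
    ev <- eval_panels(ch$lo, ch$hi)
    if (k == 2) {
      leaves$lo <- c(leaves$lo, ch$lo); leaves$hi <- c(leaves$hi, ch$hi)
    } else {
      leaves$lo <- rbind(leaves$lo, ch$lo)
      leaves$hi <- rbind(leaves$hi, ch$hi)
    }
    val <- c(val, ev$val); err <- c(err, ev$err)
    depth <- c(depth, child_depth)
  }
  tot_err <- sum(err)
  list(p = sum(val) / (2 * total_width),
       err = tot_err / (2 * total_width),
       converged = tot_err < tol_int,
       n_rays = rays_so_far,
       dirs = do.call(rbind, all_dirs),
       roots = if (length(all_roots)) do.call(rbind, all_roots)
               else data.frame(ray = integer(0), z = numeric(0)))
}

#' Integrate a normal distribution over a domain
#'
#' Computes the probability of `N(mu, Sigma)` inside an arbitrary domain
#' by the ray-trace method: the normal is whitened, the domain is traced
#' along rays through the centre, the chi-based probability on each ray is
#' computed from its crossing points ([slice_alpha()]), and the per-ray
#' contributions are accumulated over half the angular space (each ray
#' covers both directions). In 1--3 dimensions a deterministic angular
#' grid is used (composite Gauss--Legendre, refined by doubling until the
#' change is below `tol`); in higher dimensions rays are sampled
#' Monte-Carlo by normalizing standard-normal draws.
#'
#' @param normal An [nd_normal] with strictly positive-definite covariance.
#' @param domain An `nint_domain` (quadratic, implicit or explicit).
#' @param method `"auto"` (grid for k <= 3, otherwise mc), `"grid"`, or
#'   `"mc"`.
#' @param tol Absolute tolerance target for the angular integration (grid
#'   method; the refinement stops when one more doubling changes the
#'   result by less than `tol`).
#' @param n_rays Number of Monte-Carlo rays (mc method).
#' @param seed Optional integer seed for the mc method.
#' @param boundary `FALSE` (default), `"adaptive"` to keep the boundary
#'   points met on the integration rays, `"uniform"` (2d) or
#'   `"fibonacci"` (3d) for a dedicated uniform ray grid.
#' @param n_boundary Number of rays when `boundary` is `"uniform"` or
#'   `"fibonacci"`.
#' @param max_nodes Ray budget for the adaptive grid (default: 4e6 for
#'   quadratic/explicit domains whose rays are cheap to trace, 1e6 for
#'   implicit domains).
#' @return An object of class `nint_prob`: list with `p`, `p_complement`,
#'   `se` (mc only), `method`, `n_rays`, `boundary_points` (points in the
#'   original space, if requested) and `message` (diagnostics when the
#'   tolerance was not provably reached within the ray budget).
#' @examples
#' ## P(x1 > 1) for a standard 2d normal: pnorm(-1)
#' d <- quad_domain(matrix(0, 2, 2), c(1, 0), -1)
#' norm_prob(nd_normal(c(0, 0), diag(2)), d)$p
#' @export
norm_prob <- function(normal, domain, method = c("auto", "grid", "mc"),
                      tol = 1e-8, n_rays = 1e5, seed = NULL,
                      boundary = FALSE, n_boundary = 400L,
                      max_nodes = NULL) {
  stopifnot(inherits(normal, "nd_normal"), inherits(domain, "nint_domain"))
  method <- match.arg(method)
  k <- normal$k
  if (!is.null(domain$k) && domain$k != k)
    stop("dimension mismatch between normal and domain")
  if (method == "auto") method <- if (k <= 3) "grid" else "mc"
  if (method == "grid" && k > 3)
    stop("the deterministic angular grid is available only for k <= 3; ",
         "use method = 'mc'")

  batch <- make_batch_alpha(normal, domain)
  S <- sym_sqrt(normal$Sigma)
  msg <- NULL
  se <- NA_real_
  last <- NULL

  if (method == "grid") {
    if (k == 1) {
      last <- batch(matrix(1, 1, 1))
      p <- last$alpha / 2
      n_used <- 1L
      last_dirs <- matrix(1, 1, 1)
    } else {
      cheap_rays <- domain$type != "implicit"
      if (is.null(max_nodes)) max_nodes <- if (cheap_rays) 4e6 else 1e6
      ## the panel error estimator can be optimistic where alpha has
      ## square-root creases, so cheap (analytic-trace) domains target a
      ## hard safety margin below the requested tolerance
      res <- adaptive_angular(batch, k, tol, max_nodes = max_nodes,
                              init_div = if (cheap_rays) NULL
                                         else if (k == 2) 16L else 6L,
                              min_depth = if (cheap_rays) 3L else 1L,
                              safety = if (cheap_rays) 0.02 else 0.1)
      p <- res$p
      n_used <- res$n_rays
      if (!res$converged && res$err > tol)
        msg <- sprintf(paste0("adaptive grid stopped at %d rays with ",
                              "estimated error %.2e > tol = %.1e"),
                       n_used, res$err, tol)
      last <- list(alpha = NULL, roots = res$roots)
      last_dirs <- res$dirs
    }
  } else {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(as.integer(seed))
    }
    dirs <- matrix(stats::rnorm(n_rays * k), n_rays, k)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    last <- batch(dirs)
    p <- mean(last$alpha) / 2
    se <- stats::sd(last$alpha) / 2 / sqrt(n_rays)
    if (se > tol)
      msg <- sprintf(
        "Monte-Carlo standard error %.2e exceeds tol = %.1e at n_rays = %d",
        se, tol, as.integer(n_rays))
    n_used <- as.integer(n_rays)
    last_dirs <- dirs
  }

  bp <- NULL
  if (!identical(boundary, FALSE)) {
    if (identical(boundary, "uniform") || identical(boundary, "fibonacci")) {
      bdirs <- boundary_directions(k, boundary, n_boundary)
      btr <- batch(bdirs)
      dirs_used <- bdirs
      roots <- btr$roots
    } else {
      dirs_used <- if (k == 1 && method == "grid") matrix(1, 1, 1)
                   else last_dirs
      roots <- last$roots
    }
    if (nrow(roots)) {
      zn <- dirs_used[roots$ray, , drop = FALSE] * roots$z
      bp <- sweep(zn %*% S, 2L, normal$mu, "+")
    } else bp <- matrix(numeric(0), 0, k)
  }

  p <- min(max(p, 0), 1)
  structure(list(p = p, p_complement = 1 - p, se = se, method = method,
                 n_rays = n_used, tol = tol, boundary_points = bp,
                 message = msg),
            class = "nint_prob")
}

#' @export
print.nint_prob <- function(x, ...) {
  cat(sprintf("normal probability in domain: p = %.10g (method: %s)\n",
              x$p, x$method))
  if (!is.na(x$se)) cat(sprintf("  mc standard error: %.3g\n", x$se))
  if (!is.null(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

boundary_directions <- function(k, kind, n) {
  if (identical(kind, "uniform")) {
    if (k != 2) stop("uniform boundary grid is for 2d")
    th <- seq(0, pi, length.out = n + 1L)[-(n + 1L)]
    cbind(cos(th), sin(th))
  } else {
    if (k != 3) stop("fibonacci boundary grid is for 3d")
    i <- seq_len(n) - 0.5
    phi <- pi * (1 + sqrt(5)) * i
    cth <- 1 - i / n            # upper half sphere (rays cover both ends)
    sth <- sqrt(pmax(1 - cth^2, 0))
    cbind(sth * cos(phi), sth * sin(phi), cth)
  }
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
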