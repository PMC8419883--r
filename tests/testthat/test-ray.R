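test_that("ray distribution reduces to the normal in 1d and is a cdf/pdf pair", {
  z <- c(-2, -0.5, 0, 0.5, 2)
  expect_equal(ray_pdf(z, 1), dnorm(z))
  expect_equal(ray_cdf(z, 1), pnorm(z))
  for (k in c(2, 3, 7)) {
    expect_equal(ray_cdf(0, k), 0.5)
    ## nondecreasing, correct limits
    zz <- seq(-8, 8, length.out = 200)
    expect_true(all(diff(ray_cdf(zz, k)) >= 0))
    expect_equal(ray_cdf(-10, k), 0, tolerance = 1e-12)
    expect_equal(ray_cdf(10, k), 1, tolerance = 1e-12)
    ## pdf integrates to one
    expect_equal(integrate(ray_pdf, -Inf, Inf, k = k)$value, 1,
                 tolerance = 1e-7)
  }
  ## chi-square form at k = 3
  expect_equal(ray_cdf(1, 3), (1 + pchisq(1, 3)) / 2)
})

test_that("slice_alpha composes initial sign and crossings correctly", {
  expect_equal(slice_alpha(list(psi = 1, roots = numeric(0)), 2), 2)
  expect_equal(slice_alpha(list(psi = -1, roots = numeric(0)), 2), 0)
  expect_equal(slice_alpha(list(psi = 0, roots = numeric(0)), 2), 1)
  z1 <- 0.7
  expect_equal(slice_alpha(list(psi = -1, roots = z1), 3),
               2 * (1 - ray_cdf(z1, 3)))
  ## psi = 1 with roots z1 < 0 < z2 (the schematic two-crossing case)
  z <- c(-0.8, 1.3)
  expect_equal(slice_alpha(list(psi = 1, roots = z), 2),
               2 - 2 * (1 - ray_cdf(z[1], 2)) + 2 * (1 - ray_cdf(z[2], 2)))
})

test_that("norm_prob recovers closed forms", {
  ## whole space
  dom <- implicit_domain(function(x) rep(1, nrow(x)), k = 2)
  expect_equal(norm_prob(nd_normal(c(0, 0), diag(2)), dom)$p, 1)
  ## half-plane x1 > 1 under the standard normal, all dimensions
  for (k in 1:3) {
    hp <- quad_domain(matrix(0, k, k), c(1, rep(0, k - 1)), -1)
    expect_equal(norm_prob(nd_normal(rep(0, k), diag(k)), hp)$p,
                 pnorm(-1), tolerance = 1e-8)
  }
  ## correlated half-space: Phi(q0~ / |q1~|)
  set.seed(7)
  nl <- rand_normal(3)
  a <- rnorm(3); b <- rnorm(1)
  hp <- quad_domain(matrix(0, 3, 3), a, b)
  qt <- standardize_quadratic(hp, nl)
  expect_equal(norm_prob(nl, hp)$p,
               pnorm(qt$q0 / sqrt(sum(qt$q1^2))), tolerance = 1e-8)
})

test_that("domain and its inversion sum to one", {
  set.seed(8)
  for (k in 1:3) {
    nl <- rand_normal(k)
    q <- rand_quad(k)
    p1 <- norm_prob(nl, q)$p
    p2 <- norm_prob(nl, quad_domain(-q$Q2, -q$q1, -q$q0))$p
    expect_equal(p1 + p2, 1, tolerance = 2e-8)
  }
  ## 4d via Monte-Carlo rays: same rays, so complement is near-exact
  nl <- rand_normal(4)
  q <- rand_quad(4)
  p1 <- norm_prob(nl, q, method = "mc", n_rays = 2e4, seed = 1)$p
  p2 <- norm_prob(nl, quad_domain(-q$Q2, -q$q1, -q$q0), method = "mc",
                  n_rays = 2e4, seed = 1)$p
  expect_equal(p1 + p2, 1, tolerance = 1e-10)
})

test_that("rotating domain and normal together leaves the probability unchanged", {
  set.seed(9)
  nl <- rand_normal(3)
  q <- rand_quad(3)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  nl_r <- nd_normal(drop(R %*% nl$mu), R %*% nl$Sigma %*% t(R))
  q_r <- quad_domain(R %*% q$Q2 %*% t(R), drop(R %*% q$q1), q$q0)
  expect_lt(abs(norm_prob(nl, q)$p - norm_prob(nl_r, q_r)$p), 2e-6)
})

test_that("ray and generalized chi-square methods agree on random quadratics", {
  set.seed(10)
  for (i in 1:25) {
    k <- sample(1:3, 1)
    nl <- rand_normal(k)
    q <- rand_quad(k)
    expect_equal(norm_prob(nl, q)$p, normint:::quad_prob_gx2(nl, q),
                 tolerance = 1e-6)
  }
})

test_that("enlarging the implicit trace radius respects the truncation bound", {
  nl <- nd_normal(0.5, 1.3)
  f <- function(x) sin(exp(x[, 1]))
  p_small <- norm_prob(nl, implicit_domain(f, k = 1, m = 4))$p
  p_large <- norm_prob(nl, implicit_domain(f, k = 1, m = 8))$p
  bound <- 2 * (1 - ray_cdf(4, 1))
  expect_lt(abs(p_large - p_small), bound)
})

test_that("torus and two-circle integrals match membership sampling oracles", {
  nl <- demo_normal_3d()
  p <- norm_prob(nl, domain_torus(), tol = 1e-4)
  set.seed(11)
  xs <- nd_sample(4e5, nl)
  fld <- function(x) 1 - (2 - sqrt(x[, 1]^2 + x[, 2]^2))^2 - x[, 3]^2
  mb <- membership_frac(fld, xs)
  expect_lt(abs(p$p - mb), 3 * sqrt(mb * (1 - mb) / 4e5))

  nl2 <- nd_normal(c(0.2, -0.1), matrix(c(0.8, 0.3, 0.3, 0.6), 2))
  p2 <- norm_prob(nl2, domain_two_circles())
  xs2 <- nd_sample(4e5, nl2)
  fld2 <- function(x) pmax(1 - (x[, 1] + 0.75)^2 - x[, 2]^2,
                           1 - (x[, 1] - 0.75)^2 - x[, 2]^2)
  mb2 <- membership_frac(fld2, xs2)
  expect_lt(abs(p2$p - mb2), 3 * sqrt(mb2 * (1 - mb2) / 4e5))
})

test_that("Monte-Carlo rays converge on the 4d cross-polytope across seeds", {
  nl <- nd_normal(rep(0, 4), diag(4))
  dom <- domain_polyhedron(4)
  set.seed(12)
  xs <- matrix(rnorm(4e5 * 4), ncol = 4)
  mb <- mean(rowSums(abs(xs)) < 1)
  ps <- vapply(1:3, function(s)
    norm_prob(nl, dom, method = "mc", n_rays = 1e4, seed = s)$p, 0)
  r <- norm_prob(nl, dom, method = "mc", n_rays = 1e4, seed = 1)
  expect_true(all(abs(ps - mb) < 4 * r$se + 3 * sqrt(mb * (1 - mb) / 4e5)))
  ## spread across seeds shrinks with more rays
  ps2 <- vapply(1:3, function(s)
    norm_prob(nl, dom, method = "mc", n_rays = 8e4, seed = s)$p, 0)
  expect_lt(sd(ps2), sd(ps))
  ## seeded runs are reproducible
  expect_identical(
    norm_prob(nl, dom, method = "mc", n_rays = 5e3, seed = 7)$p,
    norm_prob(nl, dom, method = "mc", n_rays = 5e3, seed = 7)$p)
})

test_that("grid method refuses k > 3 and boundary points lie on the boundary", {
  nl <- nd_normal(rep(0, 4), diag(4))
  expect_error(norm_prob(nl, rand_quad(4), method = "grid"), "k <= 3")
  nl2 <- nd_normal(c(0.3, -0.2), matrix(c(1.5, 0.4, 0.4, 0.9), 2))
  disc <- quad_domain(-diag(2), c(0, 0), 1)
  r <- norm_prob(nl2, disc, boundary = "uniform", n_boundary = 100L)
  expect_gt(nrow(r$boundary_points), 0)
  expect_lt(max(abs(rowSums(r$boundary_points^2) - 1)), 1e-8)
})
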