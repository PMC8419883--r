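test_that("approximate indices reduce correctly and obey their ordering", {
  ## equal sds in 1d: all indices equal |mu_a - mu_b| / sigma
  a <- nd_normal(0, 4); b <- nd_normal(3, 4)
  dp <- dprime_approx(a, b)
  expect_equal(dp$d_a, 1.5)
  expect_equal(dp$d_e, 1.5)
  ## equal covariances in 2d: both equal the Mahalanobis distance
  S <- matrix(c(2, 0.7, 0.7, 1), 2)
  aa <- nd_normal(c(0, 0), S); bb <- nd_normal(c(1, 2), S)
  dm <- mahal_dist(aa$mu, bb$mu, S)
  dp2 <- dprime_approx(aa, bb)
  expect_equal(dp2$d_a, dm, tolerance = 1e-10)
  expect_equal(dp2$d_e, dm, tolerance = 1e-10)
  ## d_a <= d_e on 1000 random 1d and 2d pairs
  set.seed(24)
  for (i in 1:1000) {
    k <- sample(1:2, 1)
    d <- dprime_approx(rand_normal(k), rand_normal(k))
    expect_lte(d$d_a, d$d_e + 1e-12)
  }
  ## extreme sd ratio: d_a / d_e -> 1/sqrt(2)
  d <- dprime_approx(nd_normal(0, 1e8), nd_normal(1, 1))
  expect_equal(d$d_a / d$d_e, 1 / sqrt(2), tolerance = 1e-3)
})

test_that("the Bayes index is exact for equal covariances and symmetric", {
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  a <- nd_normal(c(0, 0), S); b <- nd_normal(c(1, 2), S)
  db <- dprime_bayes(a, b)
  expect_equal(db$d_b, mahal_dist(a$mu, b$mu, S), tolerance = 1e-9)
  ## equal means, unequal variances: still discriminable
  db2 <- dprime_bayes(nd_normal(0, 1), nd_normal(0, 4))
  expect_gt(db2$d_b, 0)
  expect_lt(db2$p_e, 0.5)
  ## symmetry on random pairs
  set.seed(25)
  for (i in 1:5) {
    x <- rand_normal(2); y <- rand_normal(2)
    expect_equal(dprime_bayes(x, y)$d_b, dprime_bayes(y, x)$d_b,
                 tolerance = 1e-9)
  }
})

test_that("the double-precision ceiling sits at d' of about 75", {
  realmin <- 2.2250738585072014e-308
  expect_equal(round(-2 * qnorm(realmin)), 75)
  ## just below the ceiling: p_e representable, d_b finite and exact
  db <- dprime_bayes(nd_normal(0, 1), nd_normal(74, 1))
  expect_false(db$fallback)
  expect_equal(db$d_b, 74, tolerance = 1e-6)
  ## beyond the ceiling the 1d fallback returns d_e
  dbf <- dprime_bayes(nd_normal(0, 1), nd_normal(80, 1))
  expect_true(dbf$fallback)
  expect_equal(dbf$d_b, 80)      # equal sds: d_e = separation
})

test_that("d_e converges to d_b as separation grows in 1d", {
  s <- 2   # fixed sd ratio
  seps <- c(5, 10, 20, 40)
  ratio <- vapply(seps, function(d) {
    a <- nd_normal(0, s^2 * (4 / d)^2); b <- nd_normal(4, (4 / d)^2)
    dprime_approx(a, b)$d_e / dprime_bayes(a, b)$d_b
  }, 0)
  expect_true(all(diff(abs(ratio - 1)) < 0))
  expect_lt(abs(ratio[length(ratio)] - 1), 0.02)
})

test_that("yes/no closed form handles equal-variance and variance-only cases", {
  expect_equal(yes_no_errors(0, 1, 1, 1)$p_e, pnorm(-0.5))
  yn <- yes_no_errors(0, 2, 0, 1)       # equal means, sd ratio 2
  expect_lt(yn$p_e, 0.5)
  ## random pairs match the ray-method classification to 1e-9
  set.seed(26)
  for (i in 1:5) {
    mu <- rnorm(2); sd2 <- runif(2, 0.3, 2.5)
    yn <- yes_no_errors(mu[1], sd2[1], mu[2], sd2[2])
    r <- classify_normals(list(nd_normal(mu[1], sd2[1]^2),
                               nd_normal(mu[2], sd2[2]^2)),
                          method = "ray")
    expect_equal(yn$p_e, r$p_e, tolerance = 1e-9)
  }
})

test_that("two-interval performance matches closed forms and cross-checks", {
  ## equal sds: p_c = Phi(d' / sqrt(2)) and the boundary is x1 > x2
  a <- nd_normal(0, 1); b <- nd_normal(1, 1)
  ti <- two_interval(a, b)
  expect_equal(ti$p_c, pnorm(1 / sqrt(2)), tolerance = 1e-9)
  expect_lt(max(abs(ti$boundary$Q2)), 1e-12)
  ## identical classes: chance
  tie <- two_interval(a, a)
  expect_equal(tie$p_c, 0.5, tolerance = 1e-9)
  ## gx2 and 2d ray agree on random pairs
  set.seed(27)
  for (i in 1:4) {
    mu <- rnorm(2); sd2 <- runif(2, 0.4, 2)
    aa <- nd_normal(mu[1], sd2[1]^2); bb <- nd_normal(mu[2], sd2[2]^2)
    t1 <- two_interval(aa, bb)
    t2 <- two_interval(aa, bb, method = "ray")
    expect_equal(t1$p_e, t2$p_e, tolerance = 1e-8)
  }
})

test_that("the two-interval construction scales d_e and d_a by sqrt(2)", {
  set.seed(28)
  for (i in 1:20) {
    mu <- rnorm(2); sd2 <- runif(2, 0.4, 2)
    a <- nd_normal(mu[1], sd2[1]^2); b <- nd_normal(mu[2], sd2[2]^2)
    d1 <- dprime_approx(a, b)
    ti <- two_interval(a, b)
    expect_equal(ti$d_e, sqrt(2) * d1$d_e, tolerance = 1e-9)
    expect_equal(ti$d_a, sqrt(2) * d1$d_a, tolerance = 1e-9)
  }
})

test_that("m-interval accuracy is consistent, decreasing, and correct at chance", {
  ## m = 2 equals the two-interval route
  ti <- two_interval(nd_normal(0, 4), nd_normal(1, 0.36))
  expect_equal(m_interval_accuracy(2, 0, 2, 1, 0.6), ti$p_c,
               tolerance = 1e-8)
  ## identical classes: pure guessing
  for (m in 2:4)
    expect_equal(m_interval_accuracy(m, 1, 1, 1, 1), 1 / m)
  ## decreasing in m
  accs <- vapply(2:5, m_interval_accuracy, 0, mu_a = 0, sigma_a = 2,
                 mu_b = 1, sigma_b = 0.6)
  expect_true(all(diff(accs) < 0))
  ## equal sds: matches a Monte-Carlo max-likelihood-ratio simulation
  set.seed(29)
  n <- 2e5; m <- 3
  xa <- rnorm(n, 0.8, 1)
  xb <- matrix(rnorm(n * (m - 1)), n)
  pc_mc <- mean(xa > apply(xb, 1, max))  # lr monotone in x when sds equal
  expect_lt(abs(m_interval_accuracy(3, 0.8, 1, 0, 1) - pc_mc),
            3 * sqrt(0.25 / n))
})

test_that("ROC curves pass the corners, match AUC and the farthest-point index", {
  a <- nd_normal(0, 4); b <- nd_normal(1, 0.36)
  roc <- roc_curve(a, b)
  expect_gte(min(roc$curve$fa), 0); expect_lte(max(roc$curve$fa), 1)
  ## curve effectively spans (0,0) to (1,1)
  expect_lt(min(roc$curve$hit), 1e-4)
  expect_gt(max(roc$curve$hit), 1 - 1e-4)
  ## AUC of the likelihood-ratio curve equals optimal two-interval accuracy
  ti <- two_interval(a, b)
  expect_equal(roc$auc, ti$p_c, tolerance = 1e-3)
  ## farthest point reproduces the Bayes index
  db <- dprime_bayes(a, b)
  expect_equal(roc$d_b, db$d_b, tolerance = 5e-3)
  ## random 1d pairs
  set.seed(30)
  for (i in 1:3) {
    mu <- rnorm(2); sd2 <- runif(2, 0.4, 2)
    aa <- nd_normal(mu[1], sd2[1]^2); bb <- nd_normal(mu[2], sd2[2]^2)
    r <- roc_curve(aa, bb)
    expect_equal(r$auc, two_interval(aa, bb)$p_c, tolerance = 1e-3)
    expect_equal(r$d_b, dprime_bayes(aa, bb)$d_b, tolerance = 1e-2)
  }
})

test_that("criterion-mode ROC works on normals and on samples", {
  a <- nd_normal(1, 1); b <- nd_normal(0, 1)
  roc <- roc_curve(a, b, mode = "criterion")
  ## single criterion between equal-variance normals: AUC = Phi(d'/sqrt 2)
  expect_equal(roc$auc, pnorm(1 / sqrt(2)), tolerance = 1e-3)
  set.seed(31)
  rs <- roc_curve(rnorm(4000, 1), rnorm(4000, 0), mode = "criterion")
  expect_equal(rs$auc, pnorm(1 / sqrt(2)), tolerance = 0.03)
})

test_that("equal-covariance classification recovers the equal-variance d'", {
  S <- matrix(c(1, 0.3, 0.3, 2), 2)
  a <- nd_normal(c(0, 0), S); b <- nd_normal(c(1.2, 0.4), S)
  r <- classify_normals(list(a, b))
  expect_equal(r$d_b, mahal_dist(a$mu, b$mu, S), tolerance = 1e-9)
  expect_equal(r$d_a, r$d_b, tolerance = 1e-9)
})
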