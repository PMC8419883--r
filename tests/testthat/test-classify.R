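test_that("the Bayes boundary degenerates and shifts as the algebra requires", {
  Sig <- matrix(c(1.5, 0.3, 0.3, 0.8), 2)
  a <- nd_normal(c(0, 0), Sig); b <- nd_normal(c(2, 1), Sig)
  bnd <- bayes_boundary(a, b)
  expect_lt(max(abs(bnd$Q2)), 1e-12)      # equal covariances: flat
  ## doubling p_a v_a moves only the offset, by log 2
  vs2 <- value_structure(c(2 / 3, 1 / 3))
  bnd2 <- bayes_boundary(a, b, vs2)
  expect_equal(bnd2$Q2, bnd$Q2)
  expect_equal(bnd2$q1, bnd$q1)
  expect_equal(bnd2$q0 - bnd$q0, log(2))
  expect_error(bayes_boundary(a, b, value_structure(c(0.5, 0.5),
                                                    matrix(1, 2, 2))),
               "positive")
})

test_that("two-class error rates recover the classic closed form", {
  a <- nd_normal(0, 1); b <- nd_normal(1, 1)
  r <- classify_normals(list(a, b))
  expect_equal(r$p_mat[1, 2], pnorm(-0.5), tolerance = 1e-12)
  expect_equal(r$p_mat[2, 1], pnorm(-0.5), tolerance = 1e-12)
  expect_equal(r$p_e, pnorm(-0.5))
  expect_equal(r$d_b, 1, tolerance = 1e-9)
  expect_equal(rowSums(r$p_mat), c(a = 1, b = 1))
})

test_that("1d unequal-variance rates match the noncentral chi-square closed form", {
  yn <- yes_no_errors(0, 2, 1, 0.6)
  a <- nd_normal(0, 4); b <- nd_normal(1, 0.36)
  r_gx2 <- classify_normals(list(a, b))
  r_ray <- classify_normals(list(a, b), method = "ray")
  expect_equal(yn$p_b_given_a, r_gx2$p_mat[1, 2], tolerance = 1e-12)
  expect_equal(yn$p_a_given_b, r_gx2$p_mat[2, 1], tolerance = 1e-12)
  expect_equal(yn$p_e, r_ray$p_e, tolerance = 1e-9)
  ## swap-and-relabel convention
  yn_sw <- yes_no_errors(1, 0.6, 0, 2)
  expect_equal(yn_sw$p_b_given_a, yn$p_a_given_b)
  expect_equal(yn_sw$p_a_given_b, yn$p_b_given_a)
})

test_that("gx2 and ray classification agree on random two-class problems", {
  set.seed(17)
  for (i in 1:6) {
    k <- sample(1:3, 1)
    classes <- list(rand_normal(k), rand_normal(k))
    r1 <- classify_normals(classes, method = "gx2")
    r2 <- classify_normals(classes, method = "ray")
    expect_lt(max(abs(r1$p_mat - r2$p_mat)), 1e-6)
  }
})

test_that("priors and outcome values shift the boundary and the error matrix", {
  a <- nd_normal(0, 1); b <- nd_normal(1.5, 1)
  vs <- value_structure(c(0.8, 0.2))
  r <- classify_normals(list(a, b), vs)
  r_eq <- classify_normals(list(a, b))
  ## a higher prior on class a lowers its own error rate
  expect_lt(r$p_mat[1, 2], r_eq$p_mat[1, 2])
  ## value matrix: valuing correct b twice is equivalent in the boundary
  ## to doubling its prior odds
  vsV <- value_structure(c(0.5, 0.5), matrix(c(1, 0, 0, 2), 2))
  bV <- bayes_boundary(a, b, vsV)
  vs2 <- value_structure(c(1 / 3, 2 / 3))
  b2 <- bayes_boundary(a, b, vs2)
  expect_equal(bV$q0, b2$q0)
})

test_that("three-class regions match a simulated argmax rule", {
  cls <- fixture_normals(k = 2, n_classes = 3, seed = 7)
  r <- classify_normals(cls, tol = 1e-5)
  expect_lt(max(abs(rowSums(r$p_mat) - 1)), 1e-4)
  set.seed(18)
  for (i in 1:3) {
    xi <- nd_sample(4e4, cls[[i]])
    scores <- vapply(1:3, function(j) {
      cl <- cls[[j]]
      Si <- solve(cl$Sigma)
      d <- sweep(xi, 2, cl$mu)
      -rowSums((d %*% Si) * d) / 2 -
        as.numeric(determinant(cl$Sigma)$modulus) / 2
    }, numeric(4e4))
    asg <- max.col(scores, ties.method = "last")
    emp <- tabulate(asg, 3) / 4e4
    expect_lt(max(abs(emp - r$p_mat[i, ])), 3 * sqrt(0.25 / 4e4))
  }
  ## two classes through the multi-class path reduce to the pairwise result
  r2 <- classify_normals(cls[1:2])
  expect_equal(unname(r2$p_mat[1, 1]),
               norm_prob(cls[[1]], bayes_boundary(cls[[1]], cls[[2]]))$p,
               tolerance = 1e-8)
})

test_that("swapping class labels transposes the error matrix", {
  set.seed(19)
  classes <- list(rand_normal(2), rand_normal(2))
  r12 <- classify_normals(classes)
  r21 <- classify_normals(rev(classes))
  expect_equal(unname(r12$p_mat), unname(r21$p_mat[2:1, 2:1]),
               tolerance = 1e-9)
})

test_that("no perturbed boundary beats the Bayes boundary on the true normals", {
  set.seed(20)
  a <- rand_normal(2); b <- rand_normal(2)
  vs <- value_structure(c(0.5, 0.5))
  bnd <- bayes_boundary(a, b, vs)
  p_e_opt <- classify_normals(list(a, b))$p_e
  for (i in 1:8) {
    pert <- bnd
    pert$Q2 <- pert$Q2 + matrix(rnorm(4, sd = 0.1), 2) * diag(2)
    pert$q1 <- pert$q1 + rnorm(2, sd = 0.1)
    pert$q0 <- pert$q0 + rnorm(1, sd = 0.1)
    pert$Q2 <- (pert$Q2 + t(pert$Q2)) / 2
    r <- classify_normals(list(a, b), vs, boundary = pert)
    expect_gte(r$p_e, p_e_opt - 1e-10)
  }
})

test_that("fit_normals returns ML parameters and frequency priors", {
  x <- matrix(c(-1, 1, 5, 7, 6), ncol = 1)
  labs <- c("a", "a", "b", "b", "b")
  fit <- fit_normals(x, labs)
  expect_equal(fit$classes[[1]]$mu, 0)
  expect_equal(fit$classes[[1]]$Sigma[1, 1], 1)      # divides by n, not n-1
  expect_equal(fit$classes[[2]]$mu, 6)
  expect_equal(fit$vs$priors, c(2, 3) / 5)
  ## priors 75/25
  x2 <- matrix(rnorm(100), ncol = 1)
  fit2 <- fit_normals(x2, rep(c("a", "b"), c(75, 25)))
  expect_equal(fit2$vs$priors, c(0.75, 0.25))
  ## large-n consistency
  set.seed(21)
  nl <- nd_normal(c(1, 2), matrix(c(1, 0.6, 0.6, 2), 2))
  xs <- nd_sample(2e4, nl)
  fit3 <- fit_normals(rbind(xs, xs[1:100, ] + 10),
                      rep(c("a", "b"), c(2e4, 100)))
  expect_lt(max(abs(fit3$classes[[1]]$mu - nl$mu)), 3 * sqrt(2 / 2e4) * 3)
  expect_lt(max(abs(fit3$classes[[1]]$Sigma - nl$Sigma)), 0.1)
  expect_error(fit_normals(xs, rep("a", nrow(xs))), "two classes")
})

test_that("optimize_boundary improves or retains the starting boundary", {
  set.seed(22)
  ## linearly separable clouds with a deliberately offset initial boundary
  xa <- matrix(rnorm(160, mean = 0, sd = 0.3), ncol = 2)
  xb <- matrix(rnorm(160, mean = 4, sd = 0.3), ncol = 2)
  x <- rbind(xa, xb)
  labs <- rep(c("a", "b"), each = 80)
  init <- quad_domain(matrix(0, 2, 2), c(-1, -1), 1.0)  # x1 + x2 < 1
  init$q0 <- 7                                          # badly offset
  gam <- optimize_boundary(x, labs, init)
  expect_equal(attr(gam, "value"), 1)      # 100% sample accuracy
  ## samples from the normals themselves: gamma at least as good as beta
  cls <- list(nd_normal(c(0, 0), diag(2)), nd_normal(c(1.5, 0), diag(2)))
  xs <- rbind(nd_sample(150, cls[[1]]), nd_sample(150, cls[[2]]))
  labs2 <- rep(c("a", "b"), each = 150)
  beta <- bayes_boundary(cls[[1]], cls[[2]])
  gam2 <- optimize_boundary(xs, labs2, beta)
  expect_gte(attr(gam2, "value"), attr(gam2, "init_value"))
})

test_that("heavy-tailed samples are classified at least as well by gamma as by beta", {
  ts <- fixture_t_samples(n = 200, k = 2, df = 3, seed = 5)
  fit <- fit_normals(ts$x, ts$labels)
  beta <- bayes_boundary(fit$classes[[1]], fit$classes[[2]], fit$vs)
  gam <- optimize_boundary(ts$x, ts$labels, beta, fit$vs)
  expect_gte(attr(gam, "value"), attr(gam, "init_value"))
})

test_that("decision variables preserve classification counts exactly", {
  set.seed(23)
  cls <- list(rand_normal(2), rand_normal(2))
  bnd <- bayes_boundary(cls[[1]], cls[[2]])
  x <- rbind(nd_sample(200, cls[[1]]), nd_sample(200, cls[[2]]))
  labs <- rep(c("a", "b"), each = 200)
  dv <- decision_variable(x, bnd)
  scalar_first <- dv > 0
  direct <- normint:::boundary_assign(bnd, x)
  expect_identical(scalar_first, direct)
  ## mapped normal distribution is the gx2 of the quadratic form
  params <- decision_variable(cls[[1]], bnd)
  expect_s3_class(params, "gx2_params")
  sim <- normint:::quad_eval(bnd, nd_sample(2e4, cls[[1]]))
  expect_lt(abs(mean(sim) - gx2_mean(params)), 3 * gx2_sd(params) / sqrt(2e4))
  ## equal covariances: the decision variable is linear, hence 1d normal
  S <- matrix(c(1, 0.2, 0.2, 1), 2)
  bl <- bayes_boundary(nd_normal(c(0, 0), S), nd_normal(c(1, 1), S))
  pl <- decision_variable(nd_normal(c(0, 0), S), bl)
  expect_length(pl$w, 0)
  expect_gt(pl$s, 0)
})

test_that("axis projection returns the marginal normal", {
  nl <- nd_normal(c(1, 2, 3), diag(c(1, 4, 9)))
  pr <- project_normal(nl, c(1, 0, 0))
  expect_equal(pr$mu, 1)
  expect_equal(pr$Sigma[1, 1], 1)
  pr2 <- project_normal(nl, c(0, 2, 0))    # normalized internally
  expect_equal(pr2$mu, 2)
  expect_equal(pr2$Sigma[1, 1], 4)
})
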