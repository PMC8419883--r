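## Shared generators and independent oracles for the test suite.

rand_spd <- function(k, jitter = 0.3) {
  A <- matrix(rnorm(k * k), k)
  crossprod(A) + diag(k) * jitter
}

rand_normal <- function(k) nd_normal(rnorm(k), rand_spd(k))

rand_quad <- function(k) {
  Q <- matrix(rnorm(k * k), k)
  quad_domain((Q + t(Q)) / 2, rnorm(k), rnorm(1))
}

## membership fraction of samples inside a domain given its field function
membership_frac <- function(fld, x) mean(fld(x) > 0)

## exact P(difference of two scaled noncentral chi-squares + m <= x):
## X ~ w1 chi2(k1, l1), Y ~ w2 chi2(k2, l2) (w1, w2 > 0), Z = X - Y + m
conv_cdf_oracle <- function(w1, k1, l1, w2, k2, l2, m, x)
  integrate(function(y)
    pchisq((x - m + w2 * y) / w1, k1, ncp = l1) * dchisq(y, k2, ncp = l2),
    0, Inf, rel.tol = 1e-12)$value

## closed form for p(sin(exp(x)) > 0), x ~ N(mu, sigma^2):
## x must fall in (log(2 j pi), log((2 j + 1) pi)), j = 0, 1, ...
lognormal_sin_oracle <- function(mu, sigma, jmax = 300) {
  j <- 0:jmax
  lo <- log(2 * j * pi); lo[1] <- -Inf
  hi <- log((2 * j + 1) * pi)
  sum(pnorm((hi - mu) / sigma) - pnorm((lo - mu) / sigma))
}
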