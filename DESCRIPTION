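Package: normint
Title: Integration and Classification of Multivariate Normal Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Integrates arbitrary multivariate normal distributions over
    arbitrary domains and computes Bayes-optimal classification performance
    among normal populations. Quadratic domains are handled through the
    generalized chi-square distribution of a quadratic form of a normal
    vector (parameter extraction, cdf, pdf, inverse cdf, random numbers);
    general domains are handled by a ray-trace method that whitens the
    normal, traces the domain along rays from the centre, and accumulates
    the chi-distributed probability on each ray over an angular grid or a
    Monte-Carlo ray sample. On top of these engines the package provides
    distributions of scalar and vector functions of normal vectors, Bayes
    decision boundaries with priors and outcome values, error matrices for
    two or more classes, the Bayes discriminability index and its
    root-mean-square and average-sd approximations, yes/no, two-interval
    and m-interval task performance, ROC curves, maximum-likelihood normal
    fits, sample-optimized quadratic boundaries, dimension reduction to
    scalar decision variables, and count-band tests of normal-model
    adequacy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
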