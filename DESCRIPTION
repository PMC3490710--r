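Package: pplik
Title: Prediction and Validation Profile Likelihood for Dynamic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Propagates experimental-data uncertainty into confidence
    intervals for arbitrary predictions of ordinary-differential-equation
    models via the prediction profile likelihood, and into intervals for
    the outcome of noisy validation experiments via the validation profile
    likelihood.  Instead of sampling a high-dimensional parameter space,
    a one-dimensional prediction space is scanned by constrained (or
    penalized and rescaled) maximum-likelihood optimization.  Bounded
    prediction confidence intervals for unmeasured states provide a
    data-based practical-observability analysis; Monte-Carlo coverage
    studies and experimental-design ranking are included, together with
    symbolic model declaration, simulation of noisy time-course data and
    multi-start least-squares estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    lhs,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
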