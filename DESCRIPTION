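Package: diffsamp
Title: Exact Samplers for Wiener Diffusion First-Passage Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact random-number generation from the first-passage time
    distribution of the Wiener diffusion model with two absorbing boundaries,
    the workhorse evidence-accumulation model for binary choice and response
    times. Implements adaptive rejection sampling (ARS) on a log-time change
    of variables of the defective first-passage density, together with a
    pseudo-adaptive variant, inverse transform sampling by bisection on the
    cumulative distribution, and rejection sampling with exponential,
    scaled-inverse-chi-square and inverse-Gaussian proposals. Supports
    truncation from above, sampling conditional on the response boundary, and
    trial-to-trial variability in drift rate, relative starting point and
    non-decision time. Ships a validation harness: a log-concavity scan of
    the transformed density, a Kolmogorov-Smirnov calibration study of all
    samplers, and a timing harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    graphics,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
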