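Package: memde
Title: Nonparametric Maximum-Entropy Density Estimation Scored by Order
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated nonparametric estimation of a univariate probability
    density as the exponential of a Chebyshev series. Lagrange multipliers
    are found by a funnel-diffusion random search scored against a universal,
    nearly sample-size-invariant quasi-log-likelihood built from single order
    statistics of sampled uniform random data (SURD). Includes data-driven
    censor windowing for unbounded or heavy-tailed data, hierarchical data
    augmentation for large samples, ensemble fitting with central-model
    selection, scaled quantile residual (SQR) diagnostics, a figure of merit,
    and benchmark test distributions with quantile-transform samplers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
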