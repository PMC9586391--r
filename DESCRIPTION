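Package: olinh
Title: The Odd Lomax Inverted Nadarajah-Haghighi Lifetime Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density, distribution function, quantile function, random
    generation, hazard and odds-of-failure functions for the four-parameter
    odd Lomax inverted Nadarajah-Haghighi (OLINH) lifetime distribution and
    its two-parameter inverted Nadarajah-Haghighi (INH) baseline.
    Distributional summaries (moments, incomplete moments, moment generating
    function, Renyi entropy, order statistics, quantile-based shape
    measures), maximum-likelihood estimation with profile likelihood for the
    Lomax shape and Wald intervals, Bayesian estimation under independent
    gamma priors by Metropolis-Hastings within Gibbs with highest posterior
    density intervals, goodness-of-fit model comparison
    (Kolmogorov-Smirnov, Cramer-von Mises, Anderson-Darling, AIC/CAIC/BIC/HQIC),
    a Monte-Carlo harness for estimator-recovery experiments, and a packaged
    COVID-19 full-vaccination-rate data set for 46 African countries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus
Config/testthat/edition: 3
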