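Package: testletMAT
Title: Testlet-Based Multidimensional Adaptive Testing with Random Testlet Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multidimensional computerized adaptive testing for item pools
    organized in testlets (sets of items sharing a stimulus). Implements a
    multidimensional 3PL item response model with person-specific random
    testlet effects that absorb local item dependence, D-optimal (determinant)
    testlet selection with successively expanded prior-covariance and Fisher
    information matrices, Bayes modal scoring by Fisher scoring during the
    test, Metropolis-within-Gibbs final scaling with expected a posteriori
    estimates and a Geweke-based burn-in rule, marginal maximum likelihood
    difficulty calibration, and a Monte-Carlo study driver that evaluates
    adaptive against random testlet selection under varying testlet sizes and
    testlet-effect variances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rjags,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
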