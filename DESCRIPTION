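Package: gtxscreen
Title: Integrated In Vitro Genotoxicity Screening and Potency Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated new-approach-methodology (NAM) workflow for in vitro
    genotoxicity assessment of data-poor chemicals. Implements a transcriptomic
    DNA-damage-inducing (DDI) classifier ensemble (nearest shrunken centroids with
    posterior probabilities, principal-component projection, and two-dimensional
    hierarchical clustering against a labeled reference set), micronucleus and
    multiplexed DNA-damage flow-cytometry endpoint calling with global evaluation
    factors, benchmark-concentration (BMC) modeling with trend-test prefiltering,
    an exponential/linear/polynomial/power model family selected by AIC, bootstrap
    confidence limits and gene-set median BMCs, and ToxPi-style weighted
    integration of endpoint potencies into compound rankings. A synthetic-study
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
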