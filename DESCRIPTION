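Package: ratepath
Title: Rates of Change and Causal Path-Model Selection for Bacterioplankton
    Communities Along Aquatic Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how fast bacterioplankton community
    structure and metabolism change along environmental transitions between
    connected aquatic habitats, and for comparing alternative causal pathways
    linking resource gradients to community metabolism.  Implements
    dissimilarity-based rates of change (the OLS slope of Euclidean
    dissimilarity to the head site against water transit time), DGGE
    fingerprint metrics (relative band intensities, Shannon diversity,
    presence-absence band turnover), a recursive path-model (structural
    equation model) engine with maximum-likelihood chi-square fit testing
    over a nine-model candidate library spanning Adjustment and Replacement
    response scenarios, subset analyses (per date, gradient-intensity split,
    single-resource driver), and a linear-Gaussian community simulator with
    known causal structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
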