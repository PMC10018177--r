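Package: ltcfdea
Title: Service-Efficiency Dynamics of Long-Term Care Facilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Panel efficiency analysis for long-term care facilities (and
    comparable service units): input-oriented CCR/BCC data envelopment
    analysis with returns-to-scale classification, non-oriented slack-based
    (SBM) and super-SBM efficiency for full rankings, Malmquist total factor
    productivity decomposition, quantile-state Markov and spatially
    conditioned Markov transition dynamics with Anderson-Goodman homogeneity
    tests, global and local Moran spatial autocorrelation with permutation
    inference, and censored (Tobit) regression of efficiency determinants.
    Includes synthetic-data generators with known ground truth for every
    stage and a configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), ape, survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
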