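Package: netalloc
Title: Dyadic Network Regression of Resource Allocation in Classroom Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing resource allocation (modified Dictator Game
    point allocation) within and across adolescent classroom social networks.
    Scores social-network questionnaire responses into valued relationship
    strength sociomatrices and antisymmetric reciprocation matrices, compares
    valued network densities with vertex-bootstrap standard errors and
    dyad-count degrees of freedom, fits single-network MRQAP (multiple
    regression quadratic assignment procedure) with double-semipartialing
    permutation inference, fits pooled multigroup MRQAP with class fixed
    effects, group-interaction predictors and block-restricted permutations,
    and performs directional backward elimination with main-effect protection.
    Includes a synthetic-data generator with tunable dyadic reciprocity and
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
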