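Package: urbancats
Title: Multistate Matrix Population Models for Urban Domestic Cats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic, density-dependent multistate matrix population
    models for domestic cats in urban areas. Cats are classified by life
    stage (intact or sterilized, juvenile or adult) and ownership state
    (owned, shelter, free-roaming, feral), and the annual projection matrix
    is assembled from demography and state-transition blocks with the
    vec-permutation construction. City-level parameterization requires only
    latitude, number of dwellings, and urban area; carrying capacities,
    breeding-season-driven fecundities, and density-dependent survival and
    transition rates are derived from these inputs. Includes an equilibrium
    solver, perturbation (elasticity) analysis of equilibrium abundance with
    respect to all lower-level parameters, model-validation statistics
    (tests of a 1:1 predicted-observed relationship and exact binomial
    confidence intervals), and synthetic fixture generators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
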