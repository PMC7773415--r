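Package: musclepoly
Title: Autogenerating Polynomial Models of Musculoskeletal Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximates musculotendon length and moment arms across joint
    postures with sparse multivariate polynomials whose term structure is
    selected automatically by forward stepwise regression under the corrected
    Akaike Information Criterion (AICc). A differential constraint couples the
    length polynomial to its moment-arm polynomials (moment arm as the partial
    derivative of length with respect to a joint angle), so that a single
    mutually consistent analytic model describes all kinematic variables of a
    muscle. Includes a synthetic muscle-geometry generator for posture-grid
    datasets, validation metrics with Chebyshev-based outlier screening,
    structural analysis of fitted polynomials (similarity index, power-signature
    muscle invariants, clustering and PCA), and a Hill-type isometric
    force/torque model with a kinematic-noise propagation experiment.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
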