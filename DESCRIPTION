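Package: mtpeel
Title: Statistical Mechanics of Microtubule Protofilament Peeling and Shrinkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models a microtubule protofilament as a discrete worm-like chain
    with intrinsic GDP curvature and breakable Hookean lateral bonds to its
    neighbors. Samples the tip-position free-energy landscape F(Rx) by
    Metropolis Monte Carlo and harmonic umbrella sampling with WHAM
    recombination, computes unzippering kinetics from mean first-passage-time
    integrals, and simulates microtubule shrinkage by overdamped Langevin
    dynamics of the tip coupled to stochastic subunit dissociation. Includes a
    three-protofilament generalization with per-protofilament planar
    fluctuations, GTP-cap compositions, and closed-form zero-temperature and
    semi-analytic references.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
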