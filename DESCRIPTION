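Package: coresist
Title: Joint Evolution of General and Specific Host Resistance to Endemic
    and Foreign Pathogens
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic eco-evolutionary simulator for the joint evolution
    of continuously variable (general) and single-gene (specific) host
    resistance against sterilizing pathogens with frequency-dependent
    transmission, modelled on anther-smut disease.  Implements an SI
    compartmental model over a grid of general-resistance strengths, an
    adaptive-dynamics mutation loop with scheduled introductions of the
    specific-resistance allele and of a foreign (host-shift) pathogen,
    closed-form invasion and persistence analytics, an explicit two-locus
    four-genotype recombination model with a mating matrix, parameter-sweep
    experiment presets with outcome classification, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
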