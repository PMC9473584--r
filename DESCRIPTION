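Package: phasefus
Title: Sticker-and-Spacer Mean-Field Theory and Coarse-Grained Simulation of
    ATP-Modulated Liquid-Liquid Phase Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Associative-polymer (sticker-and-spacer) mean-field theory for
    liquid-liquid phase separation of multivalent proteins such as FUS, with
    reversible Tyr-Arg cross-links and one-to-multiple ATP-Arg binding to a
    semi-grand ATP reservoir. Provides free-energy functionals with
    self-consistent bond fractions, an exact-enumeration oracle for the
    association partition function, spinodal/binodal/critical-point solvers,
    reentrant phase-diagram scans versus ATP concentration, dissolution-point
    location, and a reduced-scale coarse-grained Langevin slab simulator with
    density-profile and chain-exchange analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
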