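Package: kaishuffle
Title: Stochastic Models of ATPase-Driven Subunit Shuffling in KaiC-CI Hexamers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse nucleotide-coupled subunit exchange
    ("shuffling") between hexamers of the KaiC CI domain, the AAA+ ATPase hub of
    the cyanobacterial circadian clock. Includes event-driven and tau-leaping
    stochastic simulators of per-monomer ATP hydrolysis and nucleotide exchange
    coupled to disassembly and reassembly of competent-state hexamers, a
    distribution-distance statistic to discriminate sequential, cooperative and
    stochastic dissociation modes, synthetic ion-exchange chromatogram generation
    and seven-peak deconvolution of tag-ladder mixtures, one-phase exponential
    estimation of the shuffling rate, and contour-intersection inference of
    hydrolysis and exchange rates from ATPase activity together with either the
    shuffling rate or the competent-state fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
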