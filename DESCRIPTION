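Package: dorisim
Title: Design Toolkit and Simulator for Overhang-Addressed DNA Information Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing and simulating DNA information-storage systems
    built on ss-dsDNA strands: double-stranded payloads carrying a T7 promoter
    and a single-stranded 3' overhang that serves as a file address (the DORIS
    architecture). Provides a byte-to-codeword codec with analytic density and
    capacity models, orthogonal overhang-address design with Hamming-distance
    screening and Monte Carlo payload-conflict surveys contrasting PCR- and
    overhang-based access, an equilibrium thermodynamic model of oligo capture,
    a stochastic simulator of file separation, in vitro transcription, and
    toehold-mediated lock/unlock/rename/delete operations, and a T7
    promoter-variant pool builder with synthetic sequencing-read generation and
    readout analyses (normalized abundance, quartile position-frequency
    matrices, A/T-content groups, per-position error profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
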