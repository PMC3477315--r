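Package: discstoich
Title: Spectral-Count Stoichiometry and DED-Chain Geometry of Death Receptor Signaling Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free quantitative analysis of affinity-purified death-inducing
    signaling complex (DISC) proteomics data. Implements identification filtering
    (peptide/protein probability, Mascot ion score, parent-ion mass error,
    control subtraction and contaminant exclusion), spectral abundance factor
    (SAF) and normalized SAF (NSAF) quantitation, replicate aggregation, and
    FADD-normalized grouped stoichiometry. A rigid-body geometry module derives
    the intramolecular DED1-DED2 interface transform from tandem death effector
    domain coordinates, propagates it into a DED-chain model, and characterizes
    the chain's helical geometry by screw-axis decomposition. A synthetic-data
    module simulates replicate treated/control spectral-count tables from a known
    complex composition and toy coordinate sets with known transforms, so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
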