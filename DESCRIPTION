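Package: protchar
Title: In Silico Physicochemical and Structural Characterization of Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence- and structure-based characterization of proteins,
    developed around the two secreted Aspergillus niger phytases (3-phytase A,
    PDB 3K4Q, and 3-phytase B, PDB 1QFX). Computes composition-based
    physicochemical properties (molecular weight, theoretical isoelectric
    point by Henderson-Hasselbalch net-charge bisection with the
    Bjellqvist/ProtParam pKa set, GRAVY, aliphatic index, charged-residue
    tallies), the Guruprasad instability index and N-end-rule half-life,
    Kyte-Doolittle and accessibility sliding-window profiles,
    N-glycosylation sequon and histidine-acid-phosphatase motif scans,
    Kolaskar-Tongaonkar antigenic determinants, a minimal PDB reader,
    distance-based lysine glycation classification with cross-method
    agreement statistics, a simplified Kabsch-Sander secondary-structure
    assigner, inter-chain interface detection, docked-pose hydrogen-bond
    enumeration, and deterministic synthetic fixtures for testing all of the
    above without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    digest,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
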