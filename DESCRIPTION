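Package: kaiabc
Title: Coevolution, Binding Thermodynamics and Phosphoform Dynamics of the
    Cyanobacterial KaiABC Clock
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the dynamic KaiA-KaiC interaction of the
    cyanobacterial circadian oscillator. Reads, concatenates and annotates
    protein alignments of the three clock proteins; builds neighbor-joining
    trees and computes per-column relative evolution rates under empirical
    amino-acid substitution models; detects co-varying column pairs with
    physicochemical property scales and assembles contact-restricted
    co-varying residue clusters; solves the two-step KaiA-KaiC binding
    equilibrium (apparent and combined dissociation constants); and
    simulates the KaiC phosphoform oscillator with an explicit KaiA-KaiC
    binding equilibrium, including period extraction and concentration
    robustness scans. A synthetic-data module generates trees, alignments
    with planted co-varying pairs, toy structures and oscillation fixtures
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    deSolve,
    igraph,
    phangorn,
    seqinr,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
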