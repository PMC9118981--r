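Package: cyaclear
Title: Enzymatic Cyanuric Acid Remediation Analytics for Pool Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for enzymatic removal of cyanuric acid (CYA) from
    chlorinated recreational water. Identifies cyanuric acid hydrolase (CAH)
    candidates in protein FASTA by a diagnostic C-terminal motif and conserved
    anchor arginines; models pool-chlorine speciation, reductant dosing and the
    electron balance of biuret oxidation by hypochlorite; fits linear standard
    curves for the melamine-cyanurate and DPD plate assays; fits Michaelis-Menten
    kinetics and simulates CYA depletion progress curves; and deconvolutes
    stable-isotope GC/MS ion tables (m/z 28/29/30 and 44/45/46) into the fraction
    of intra- versus intermolecular dinitrogen formation. Ships seeded synthetic
    generators for every input so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
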