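Package: rpfdp
Title: NOESY-Based RPF-DP Structure Quality Scores and RDC Q Factors for
    Protein NMR
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model-versus-data validation for protein NMR structures.
    Compares short interproton distances in a coordinate model (single
    conformer or multi-model ensemble) against unassigned NOESY peak
    lists plus chemical-shift assignments, producing recall, precision,
    F-measure and the normalized Discriminating Power (DP) score, with
    per-residue violation maps.  Fits molecular alignment tensors to
    residual dipolar couplings by singular-value decomposition and
    reports RDC Q scores.  Generates ambiguous contact lists from
    unassigned NOESY peaks by chemical-shift matching.  Includes an
    ideal-geometry hydrogen builder, pseudoatom r^-6 summation
    distances, readers for PDB coordinates, NMR-STAR shift loops, XEASY
    and Sparky peak lists, and a fully synthetic NMR benchmark
    generator so every score is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
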