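Package: ribotriage
Title: Triage of RNA Motif-Small Molecule Interactions into RIBOTAC Degrader Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational triage of RNA-motif/small-molecule selection data into
    ribonuclease-targeting chimera (RIBOTAC) degrader candidates. Implements a
    canonical representation of two-strand RNA structural motifs (internal loops,
    bulges) with parsing of the 5'/3' loop notation, enumeration and motif-class
    profiling of a 3x3 internal-loop selection library, pooled two-proportion
    enrichment statistics (Z_obs) with bound-motif calling and LOGO matrices,
    transcriptome-wide motif mapping onto hairpin structure databases with
    Drosha/Dicer functional-site annotation, RNase L UNN cleavage-site scanning
    with a stem-distance eligibility rule, and chemical-novelty profiling
    (Tanimoto similarity, physicochemical descriptors, scaffold classes). A
    synthetic-data module generates every input with planted ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
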