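Package: channelstruct
Title: Structure-Based Alignment and Pore Assessment of Ion Channel
    Transmembrane Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for global structural comparison of tetrameric ion
    channel transmembrane (TM) domains. Provides fragment-seeded,
    TM-score-optimizing pairwise structural alignment run bidirectionally;
    projection of pairwise alignments onto a reference structure to build a
    structure-based multiple sequence alignment; single-linkage clustering
    of TM-distance matrices; HOLE-style pore-radius profiling with
    pore-lining residue assignment; DSSP-style secondary-structure
    assignment including pi-helix surveys; selectivity-filter and
    ligand-pocket motif comparison with BLOSUM62 identity/similarity
    scores; and a synthetic-structure generator (ideal helices, C4
    four-helix pores, perturbed structure families) so the whole pipeline
    is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
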