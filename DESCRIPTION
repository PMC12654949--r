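Package: knotlayer
Title: Pseudoknot Layer Decomposition and Coloring Scripts for RNA 3D
    Structures
Version: 0.1.0
Authors@R:
    person("Knotlayer", "Developers", email = "knotlayer@example.org",
           role = c("aut", "cre"))
Description: Extracts base pairs from RNA tertiary structures (PDB/mmCIF,
    via a built-in geometric detector) or ingests pre-computed annotations
    (RNAView text, DSSR JSON), decomposes each chain's pair set into
    pseudoknot-free layers by iterated maximum-cardinality non-crossing
    subset extraction (Nussinov-style dynamic programming), and renders the
    layers as PyMOL/Chimera coloring scripts, extended dot-bracket strings
    with bracket families, and corpus-level layer statistics. Includes a
    seeded generator of ground-truthed synthetic fixtures (planted
    multi-layer pair sets, idealized duplex coordinates, annotator-output
    files) and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
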