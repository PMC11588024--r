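Package: motifcorr
Title: Correspondence and Geometric Comparison of RNA 3D Motifs Across
    Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Retrieves corresponding sets of nucleotides (motif instances)
    across many RNA 3D structures of the same molecule or RNA family,
    compares all instances with a geometric discrepancy metric built on
    base centers and base orientation frames, orders the instances so
    similar conformations sit next to each other, annotates within-motif
    stacking and pairing plus neighboring chains, and exports an instance
    table, an ordered discrepancy matrix with heatmap, and superposed
    coordinates. Includes a synthetic mmCIF fixture generator with
    controlled rigid motions, per-base rotations, coordinate noise,
    indels and missing atoms, so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
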