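Package: kinanchor
Title: Reference-Anchored Conservation Analysis of WEE1-Family Kinases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the conservation of protein-kinase functional
    sites across a sequence family, anchored to the residue numbering of a
    chosen reference (the human WEE1A kinase by default). Provides global
    pairwise alignment with affine gaps, progressive multiple alignment with
    end trimming, mapping of alignment columns onto reference residue numbers,
    a curated WEE1 functional-site catalog (G-loop glutamate, gatekeeper,
    catalytic aspartate, DFG/DLG and EGD motifs, substrate-docking arginines)
    with physicochemical substitution classification and functionality flags,
    neighbor-joining trees with midpoint rooting and Newick import/export,
    Kabsch superposition of structures and catalytic-pocket access
    measurements on PDB coordinates, and synthetic-data generators with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
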