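Package: rigidcryst
Title: Rigidity Analysis of Protein Assemblies and Crystal Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Builds biological assemblies, unit cells and finite supercells
    from PDB-format structures using crystallographic symmetry (a registry of
    the 230 space groups is generated from shipped generator triplets by
    group closure), derives a body-bar-hinge mechanical model from covalent
    bonds, hydrogen bonds and hydrophobic contacts, decomposes it into rigid
    clusters with a (6,6) pebble game on the body-bar multigraph, and
    tabulates and classifies how rigidity aggregates across assembly levels
    (asymmetric unit, unit cell, 2x1x1 and 2x2x1 crystals). Includes a
    generator for small synthetic molecules and toy crystals with known
    ground truth, and a command-line entry point for the full pipeline.
License: MIT
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
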