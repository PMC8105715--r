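Package: memfoot
Title: Membrane Footprint and Protein-Lipid Fingerprint Analysis for
    Coarse-Grained Bilayer Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for coarse-grained molecular-dynamics
    simulations of membrane proteins that deform the bilayer, built around
    the membrane footprint of the mechanosensitive channel Piezo1.
    Implements flood-fill (branching-network) leaflet assignment of lipid
    headgroup beads, membrane-dome depth statistics and leaflet height
    maps, z-summed two-dimensional protein and lipid density maps,
    per-residue protein-lipid contact profiles with significance cutoffs,
    the preferential lipid-binding coefficient delta-L, and CRAC/CARC
    cholesterol-recognition motif scanning of protein sequences.  A
    seeded synthetic generator produces curved two-leaflet bilayers with
    a parameterised trilobed dome, planted protein-lipid contacts and
    motif-bearing sequences, providing ground truth for every analysis.
    Reads GRO/PDB structures and multi-frame GRO trajectories; writes
    TSV tables and JSON summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
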