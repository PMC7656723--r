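Package: posegrep
Title: Geometric and Substructure Filtering of Docked Small-Molecule Poses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-docking filtering of virtual-screening poses. Every docked
    pose of every compound is tested against user-defined filters, each
    combining a SMARTS substructure pattern, a 3D query point (given as a
    coordinate or anchored to a named receptor atom), a distance cutoff, and
    an optional exclude flag; a compound passes when at least one of its
    poses satisfies all filters. Reads receptors in PDB/PDBQT format and
    docked poses in PDBQT, PDB, or SDF format, assigns bond orders
    geometrically, from SMILES templates, or via an external converter, and
    computes virtual-screening enrichment metrics (enrichment factors,
    top-n hit counts, percentile ranks) on ranked, labelled libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
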