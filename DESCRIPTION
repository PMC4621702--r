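Package: plens
Title: Ensemble Analysis of Protein-Ligand Crystal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic analysis of ensembles of pre-aligned protein-ligand
    crystal structures of a single target. Extracts ligand pharmacophore
    points and fragments, clusters waters, pharmacophores, fragments,
    residue conformations and ligand binding sites with a distance-penalised
    DP-means algorithm, and produces ranked per-ligand summary tables of
    feature conservation, water displacement and residue movement. Includes
    a seeded synthetic-ensemble generator with planted ground truth for
    validation, and a command-line entry point for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    igraph,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'chem.R'
    'clustering.R'
    'features.R'
    'fingerprints.R'
    'fixtures.R'
    'io.R'
    'pipeline.R'
    'summary.R'
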