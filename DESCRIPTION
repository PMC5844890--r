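Package: pocketprobe
Title: Probe Affinity Maps, Binding-Constant Estimation and Structure
    Comparison for Ligand Design at Protein Pockets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for structure-guided ligand design at protein binding
    pockets. Computes GRID-style molecular interaction fields (five chemical
    probes combining Lennard-Jones, Coulombic and geometry-based hydrogen-bond
    terms on a regular grid), extracts favourable binding regions as
    26-connected components, and decomposes protein-ligand interaction
    energies per residue. Estimates 1:1 association constants from direct
    titrations, fluorescence displacement series and centrifugation
    competition experiments by exact mass-action equilibrium solving.
    Includes Kabsch superposition with C-alpha matching, ligand contact and
    hydrogen-bond inventories, readers and writers for PQR, PDB, OpenDX and
    CSV assay tables, and synthetic-data generators (toy pockets with
    analytic fields, simulated binding assays) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
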