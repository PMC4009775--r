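Package: confree
Title: Conformational Free-Energy Analysis of Protein Structural Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates conformational free energies of protein structural
    ensembles with an implicit-solvent GBSA energy model (Hawkins
    pairwise-descreening generalized Born, Shrake-Rupley solvent-accessible
    surface area, and classical force-field terms) combined with a
    conformational entropy estimator based on per-torsion dihedral-angle
    histograms. Provides multi-model PDB and topology input/output, atom
    selections, Kabsch superposition and RMSD analysis, metal-water contact
    counting, principal-component analysis of ensembles with equal-arc-length
    waypoint selection along conformational pathways, free-energy profiles
    along such pathways, replicate aggregation, and a synthetic-ensemble
    generator with analytic ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), bio3d, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
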