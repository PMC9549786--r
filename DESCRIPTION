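Package: ligsphere
Title: Template-Based Protein Binding Site Detection with
    Ligand-Environment Spheres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects ligand binding sites in protein structures by local
    structural alignment against a library of "sphere" templates, where
    each template is the protein environment (residues within 12 Angstrom)
    of a ligand observed in an experimentally solved complex.  Matches are
    scored with residue-level (GDT/LCS combined) and all-atom (GDC)
    similarity metrics, template ligands are transplanted into detected
    pockets by the rigid alignment transform, contact and steric-clash
    statistics are computed, matches are filtered by printed acceptance
    thresholds and merged into consensus pocket clusters, and predicted
    binding residues can be evaluated against unified-binding-site
    references with Matthews correlation and F scores.  A deterministic
    synthetic-fixture generator provides toy holo/apo complexes and decoy
    structures so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
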