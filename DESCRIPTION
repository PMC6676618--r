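Package: fragcoord
Title: Fragment-Based 3D Coordinate Generation for Small Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates three-dimensional coordinates for molecules given as
    SMILES by rigid placement of fragment geometries mined from 3D structure
    corpora. Molecules are cut at rotatable bonds into rigid fragments; a
    flat-file fragment database keyed by canonical SMILES (with a byte-offset
    index) supplies known geometries, an auxiliary tier of generic ring
    templates covers near-misses, and remaining atoms are placed one by one
    from hybridization-based valence geometry rules and covalent radii.
    Includes library construction from SDF corpora, stereochemistry
    enforcement and validation via InChIKey round trips, a conformer
    evaluation suite (symmetry-aware heavy-atom RMSD, internal coordinate
    errors, torsion fingerprint deviation), and deterministic built-in test
    fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    igraph,
    Rcpp,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
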