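# fragcoord

Fast fragment-based 3D coordinate generation for small molecules, in R.

Generating a sensible three-dimensional structure from a SMILES string is the
first step of almost every molecular-modeling workflow — docking, force-field
simulation, property prediction. Rule-based builders place atoms one at a
time from idealized valence geometry and struggle with rings; distance
geometry is accurate but slow. `fragcoord` implements the fragment-based
approach: rigid substructures whose geometry has been observed before are
placed *whole* from a database, and only the flexible connections between
them are built by rules.

The pipeline is:

1. **Fragmentation.** The query molecule is cut at every *rotatable bond*
   (single, acyclic, both heavy-atom degrees ≥ 2; amide C(=O)–N kept rigid).
   The connected pieces that remain contain no internal rotors, so one stored
   conformation per piece suffices.
2. **Library lookup.** Each fragment with ≥ 5 heavy atoms is keyed by its
   canonical SMILES (cut bonds capped with implicit hydrogens) and looked up
   in a flat-file geometry database through a key → byte-offset index. On a
   miss, the fragment is tested against an auxiliary tier of *generic ring
   templates* (SMARTS patterns with idealized ring geometry: planar aromatic
   5/6-rings, chair cyclohexane, envelope cyclopentane, crown macrocycles).
3. **Stitching.** Atoms are visited in depth-first order. A matched fragment
   is placed rigidly: the anchor atom sits at the ideal bond length
   `r(A) + r(B)` (single-bond covalent radii, scaled ×0.915 aromatic, ×0.87
   double, ×0.78 triple) along an open valence direction of its placed
   neighbor (sp 180°, sp² 120°, sp³ 109.47°), with the residual spin fixed by
   an anti (180°) torsion convention. Unmatched atoms are placed one by one
   by the same rules.
4. **Audit and stereo.** Ring-closure bonds longer than 1.5× ideal are
   flagged (never silently fixed); hydrogens are placed on the remaining
   valence directions; declared stereochemistry is enforced by comparing
   each center's signed volume against its declared parity and rigidly
   swapping/reflecting the smallest substituent branches on mismatch.

The evaluation module implements the standard metric suite for comparing a
generated conformer with a reference: symmetry-aware heavy-atom RMSD
(optimal Kabsch superposition minimized over graph automorphisms), mean
bond/angle/torsion errors, torsion fingerprint deviation (TFD, in [0,1]),
and stereochemistry success as an InChIKey round trip. Batch aggregates
follow the convention that means are computed over stereo-successful
molecules only.

Chemistry perception (SMILES parsing, canonicalization, aromaticity, SMARTS)
is delegated to Open Babel via ChemmineOB; InChIKeys come from the `obabel`
command-line tool. Everything else — fragmentation, the library format, the
builder, the metrics — is implemented here.

## Worked example

A toy library is built from the package's deterministic fixture corpus
(idealized benzene, chair cyclohexane, envelope cyclopentane, pyridine,
naphthalene, biphenyl, a 12-membered macrocycle, …, three copies each), then
cumene is generated:

```r
library(fragcoord)

lib <- build_library(build_fixture_corpus(n_copies = 3))
lib
#> <fragment_library> 6 fragments (in memory)

res <- generate_coordinates("CC(C)c1ccccc1", lib)
res$report
#> <build_report> 6 fragment atoms, 3 rule atoms, 0 long closure(s), 0 stereo correction(s)
```

The benzene ring (6 atoms) was placed in one step from the stored template;
the isopropyl group (3 atoms, below the 5-atom library threshold) was built
by rules. `res$mol$coords` holds the coordinates in Å; `write_sdf(res$mol,
"out.sdf")` writes a V2000 SD file.

How much does the fragment database buy? Regenerating cyclohexane with the
library reproduces the stored chair exactly, while the pure rule path cannot
close a saturated ring:

```r
ref <- idealized_geometry("cyclohexane_chair")
heavy_atom_rmsd(ref, generate_coordinates("C1CCCCC1", lib)$mol)
#> [1] 1.167935e-15
heavy_atom_rmsd(ref, generate_coordinates("C1CCCCC1", build_library(list()), NULL)$mol)
#> [1] 1.741
```

(The failed ring closure is not hidden: it is reported in
`report$long_closure_bonds`, mirroring the known macrocycle failure mode of
fragment stitching.)

A thin command-line front end is included:

```sh
Rscript inst/scripts/fragcoord fragments --smiles "c1ccccc1-c1ccccc1"
#> c1ccccc1  6  library-eligible
#> c1ccccc1  6  library-eligible
Rscript inst/scripts/fragcoord lib-build --sdf corpus.sdf --out db.txt --index db.idx
Rscript inst/scripts/fragcoord gen3d --smiles inputs.smi --lib db.txt --index db.idx --out out.sdf
Rscript inst/scripts/fragcoord eval --ref ref.sdf --gen out.sdf --smiles inputs.smi --out report.tsv
```

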