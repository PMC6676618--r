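---
title: "Fragment-based 3D coordinate generation: model, conventions, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based 3D coordinate generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragcoord)
```

## The method

A molecule's conformational freedom lives almost entirely in its rotatable
bonds. Everything between two rotatable bonds — a ring system, a conjugated
or amide-linked unit, a terminal group — is effectively rigid, so a single
observed 3D geometry of that substructure can be reused wherever it occurs.
`fragcoord` turns this observation into a coordinate generator:

* **Fragmentation** cuts the query at every rotatable bond. The definition
  used throughout (library build and query alike) is: single bond order, not
  aromatic, not in a ring, both endpoints with heavy-atom degree at least 2,
  and not an amide C(=O)–N bond. The amide exclusion keeps planar peptide
  units inside one fragment; it is a convention, not a law of nature, and is
  exposed as `amide_rotatable = TRUE` for sensitivity analysis. `min_atoms`
  (default 5) counts heavy atoms: the whole point of a stored fragment is to
  place many atoms at once, and hydrogens are re-derived anyway.

* **The library** maps canonical fragment SMILES to one stored geometry.
  During a corpus build every eligible fragment occurrence is counted
  (including repeats within one molecule; `count_per_molecule = TRUE` gives
  the once-per-molecule alternative) and a key is admitted once its count
  reaches `min_count` (default 3) — a light guard against corpus artifacts.
  The stored conformation is the *first* seen in stream order; later
  occurrences never replace it, so a library build is order-deterministic.
  Possible refinements such as consensus geometries over conformer clusters
  are deliberately out of scope.

* **Lookup** is two-tiered: exact canonical-SMILES key first, then generic
  ring templates (SMARTS patterns carrying idealized ring coordinates).
  The tier order is fixed — exact before generic — since the generic tier is
  an approximation net, not a competitor. A generic template wins if one of
  its SMARTS matches covers *all ring atoms and all ring bonds* of the
  fragment. The bond condition matters: the 10-atom perimeter cycle of a
  fused bicyclic like naphthalene would otherwise "cover" all ring atoms of
  a 10-ring template while the fusion bond became an absurd transannular
  chord. Fused systems that miss both tiers fall to the rule builder, whose
  geometry for them is honest but poor — visible in the closure audit rather
  than papered over.

* **Stitching** visits atoms in depth-first order from the first input atom,
  neighbors in ascending input index. A matched fragment is placed rigidly
  (rotation + translation only; internal distances are preserved to
  floating-point precision). Everything else is placed one atom at a time.

* **Auditing, hydrogens, stereochemistry** close the pipeline (next
  sections).

## Geometric conventions

Every free choice in the builder is pinned by a deterministic convention, so
identical inputs give byte-identical SD output:

* first atom at the origin; first bond direction +z; first azimuthal
  reference +x;
* ideal bond length = sum of single-bond covalent radii (Cordero consensus
  values: C 0.76 Å, N 0.71, O 0.66, H 0.31, S 1.05, …) scaled by bond order:
  ×1.00 single, ×0.915 aromatic, ×0.87 double, ×0.78 triple. With the carbon
  radius these reproduce benzene ≈ 1.39 Å, ethene ≈ 1.32 Å, ethyne ≈ 1.19 Å;
* valence directions from hybridization: sp linear (180°), sp² trigonal
  planar (120°), sp³ tetrahedral (109.47°). Hybridization itself is a pure
  graph rule — sp for a triple bond or two doubles, sp² for aromatic atoms or
  one double, sp³ otherwise for common organic elements — and never looks at
  coordinates. (This classifies an amide nitrogen as sp³; the pyramidal
  hydrogen it gets is a known idealization.)
* free torsions are set *anti* (180°) relative to the highest-index placed
  reference substituent. The fragment-spin about an anchor bond uses the
  same rule. An anti default produces extended chains, which matches how
  such builders behave in practice; no torsion-preference model is applied.
* when a stereocenter's remaining valence direction would be nearly coplanar
  with its three existing substituents (a geometry only reachable through a
  distorted ring closure), the direction falls back to the substituent-plane
  normal: a flattened center has no defined handedness and would be
  unreadable by any stereo perceiver.

## Ring closures

Sequential placement cannot guarantee that both ends of a ring meet: a
macrocycle stitched from small pieces, or any rule-built saturated ring,
ends with a closure bond far from its ideal length. `close_rings()` measures
every bond not traversed during placement and *flags* those beyond 1.5× the
ideal length in `report$long_closure_bonds`. Nothing is silently fixed —
repairing geometry is the job of a downstream force-field optimizer, for
which `generate_batch()` output is the input. This mirrors the documented
failure mode of fragment stitching on macrocycles and keeps it observable.

## Stereochemistry

Declared tetrahedral parities are carried through parsing (MDL atom parity,
neighbors in ascending index, implicit hydrogen last; cut substituents at
fragment boundaries move into the implicit-hydrogen slot with the
permutation sign tracked). Declared double-bond configurations are stored as
(bond, reference substituents, cis/trans); stereogenic double bonds whose
configuration the input left unspecified are recognized as such and never
"enforced".

After hydrogen placement, `enforce_stereo()`:

1. computes each declared center's signed volume over its four ordered
   substituents and compares the sign with the declared parity
   (counterclockwise ⇔ positive — the convention is calibrated against the
   engine's own 3D output and re-verified in the test suite);
2. on mismatch, swaps the two smallest substituent branches that lie in
   distinct components of the graph minus the center, by rigid rotations
   about the center — rigid moves cannot corrupt stereo elsewhere;
3. where no swap pair exists (a ring-fusion center whose only detachable
   substituent is its hydrogen) or where the center is flattened, the
   smallest detachable branch is instead moved onto a clean tetrahedral
   position on the declared side;
4. declared cis/trans is checked via the reference torsion and fixed by a
   180° rotation of the smaller side about the double-bond axis. Fully
   ring-locked centers are logged as uncorrectable.

Success is defined operationally: the InChIKey of the input SMILES must
equal the InChIKey of the generated 3D structure (stereo perceived from
coordinates). Keys come from the `obabel` CLI, whose InChI output matches
the reference InChI distribution.

## The evaluation suite

* **RMSD**: heavy atoms only, optimal rigid superposition (Kabsch, proper
  rotations only), minimized over graph automorphisms so that, e.g., a
  benzene rotated in labeling does not score 1.5 Å against itself. The
  automorphism set is enumerated with VF2 under element/charge vertex colors
  and bond-order edge colors, capped at 10⁴ (identity fallback with a
  warning). An identity-only mode is kept for comparison; symmetry-aware is
  never larger.
* **Internal coordinates**: mean absolute deviations over all heavy-atom
  bonds, all bonded angle triples, and all bonded torsion quadruples
  (circular difference mapped to [0, 180°]). Averaging over *all* quadruples
  rather than only rotors is a deliberate, stated choice so the number is
  interpretable without a rotor definition.
* **TFD**: per torsion bond (acyclic bonds between non-terminal heavy atoms,
  plus ring bonds), the minimal circular deviation over all reference
  substituent pairs — damping the effect of symmetric substituents — divided
  by 180°, averaged with weights 1/(1 + d) where d is the bond's topological
  distance from the molecule's graph center. This is a self-contained
  variant of the published torsion-fingerprint idea: hydrogen-free,
  normalized to [0, 1], zero iff torsionally identical, and 1.0 for the
  single-torsion anti-vs-eclipsed case. Its absolute values are not
  interchangeable with other implementations' and are meant for within-suite
  comparison.
* **Batch aggregation** averages metrics over stereo-successful molecules
  only (the convention for this metric family); `include_failures = TRUE`
  exists for sensitivity analysis.

## The fixture world, and what it does not show

All tests and the acceptance script run on a built-in deterministic corpus:
ten analytically constructed geometries (regular-hexagon benzene, standard
chair, envelope cyclopentane, crown 12-ring, idealized acyclic molecules),
emitted in triplicate with optional seeded jitter on copies after the first,
plus a 38-entry stereochemistry suite (single and multiple R/S centers,
cis/trans and diene configurations, ring, ring-fusion and macrocycle
centers, enantiomer and diastereomer pairs — with expected InChIKeys
computed at suite-build time, never hard-coded).

This world exercises every code path: exact hits, generic-ring rescues, pure
rule placement, first-conformer policy, index seeks, stereo enforcement,
closure flagging. What it cannot show is performance on *real* crystal-
structure diversity: drug-like molecules have conformational preferences,
crowded substitution, and ring geometries that no idealized corpus contains.
Passing here demonstrates the machinery is correct and deterministic, not
that accuracy on experimental benchmarks matches any published figure. The
problem sizes (10 fixtures × 3 copies; 38-molecule stereo suite; 100 random
rigid transforms; 50 random non-member keys) were chosen to keep the full
suite under a minute while covering each contract.

## Numerical and engine notes

* Library coordinates are serialized to 4 decimal places (0.1 mÅ), far below
  any geometric tolerance used anywhere.
* One canonicalization engine (Open Babel) is used for both library keys and
  query keys; keys never cross engines. The canonical *atom order* needed to
  transfer template coordinates is defined as the atom order of the
  canonical SMILES string itself, recovered by a deterministic colored-graph
  isomorphism (element, charge, hydrogen count, bond order) between the
  re-parsed key and the fragment. For symmetric fragments any of the
  equivalent matches yields a congruent geometry; handedness is restored by
  the stereo stage.
* A 0D connection table cannot express cis/trans double-bond stereo, so a
  fragment key computed on the query side carries tetrahedral parity but not
  E/Z. The rotatable-bond definition cuts away the reference substituents
  of acyclic stereo double bonds in essentially every molecule, so in
  practice this surfaces — rarely — as an exact-tier miss (the fragment then
  falls to the generic or rule tier), never as a wrong geometry.
* Degenerate inputs are defined, not special-cased: a single-atom molecule
  sits at the origin with tetrahedral hydrogens; an empty library is a valid
  library; a molecule with no torsions has TFD 0 (with a note); an empty
  evaluation batch reports n = 0 with undefined means.

## Known limitations

* Inter-fragment torsions are always anti; no torsion-preference statistics
  are mined, so folded experimental conformers will differ from generated
  extended ones even when every fragment is placed perfectly.
* Rule-built rings do not close (by design — flagged, not fixed); a
  downstream optimizer hook is the intended consumer.
* Amide nitrogens are treated as sp³ by the graph rule, giving pyramidal
  N–H placement.
* The generic-ring tier ships idealized monocycle templates only; fused
  polycyclic systems rely on the exact tier or degrade to rules.
* Metals and hypervalent centers beyond the covalent-radius table are
  rejected or handled by geometric fallbacks with a log entry.
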