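# Fragmentation: cut molecules at rotatable bonds into rigid fragments and
# key them by canonical SMILES. Both the library builder and the query
# pipeline use exactly this decomposition, so keys always match by
# construction.

#' Find rotatable bonds
#'
#' A bond is rotatable iff it is single-order, not aromatic, not in a ring,
#' both endpoints have heavy-atom degree >= 2, and it is not an amide C(=O)-N
#' bond (amides are kept rigid by default; set `amide_rotatable = TRUE` for
#' the alternative convention).
#'
#' @param mol a `molgraph`.
#' @param amide_rotatable treat amide C-N bonds as rotatable.
#' @return integer vector of bond row indices (possibly empty).
#' @examples
#' length(find_rotatable_bonds(parse_smiles("CCO")))   # 0
#' length(find_rotatable_bonds(parse_smiles("CCCC")))  # 1
#' @export
find_rotatable_bonds <- function(mol, amide_rotatable = FALSE) {
  b <- mol$bonds
  if (!nrow(b)) return(integer(0))
  deg <- heavy_degree(mol)
  cand <- which(b$order == 1L & !b$aromatic & !b$in_ring &
                  deg[b$a] >= 2L & deg[b$b] >= 2L)
  if (!amide_rotatable && length(cand)) {
    el <- mol$atoms$element
    has_carbonyl <- function(c_idx, n_idx) {
      # c_idx is carbon double-bonded to O (not the N side)
      k <- which((mol$bonds$a == c_idx | mol$bonds$b == c_idx) & mol$bonds$order == 2L)
      other <- ifelse(mol$bonds$a[k] == c_idx, mol$bonds$b[k], mol$bonds$a[k])
      any(el[other] == "O")
    }
    is_amide <- vapply(cand, function(k) {
      i <- b$a[k]; j <- b$b[k]
      (el[i] == "C" && el[j] == "N" && has_carbonyl(i, j)) ||
        (el[j] == "C" && el[i] == "N" && has_carbonyl(j, i))
    }, logical(1))
    cand <- cand[!is_amide]
  }
  cand
}

#' Cut a molecule into rigid fragments
#'
#' Fragments are the connected components of the heavy-atom graph after
#' deleting all rotatable bonds. Every heavy atom belongs to exactly one
#' fragment. Components with at least `min_atoms` heavy atoms are flagged
#' library-eligible; smaller ones fall to the rule-based builder.
#'
#' @param mol a `molgraph`.
#' @param min_atoms minimum heavy-atom count for library eligibility.
#' @param amide_rotatable passed to [find_rotatable_bonds()].
#' @return a list of fragment matches, ordered by smallest member atom index;
#'   each is a list with `atom_indices` (ascending), `key` (canonical SMILES
#'   of the induced subgraph), `map` (parent atom index per canonical
#'   position), `n_atoms`, and `eligible`.
#' @export
fragment_molecule <- function(mol, min_atoms = 5L, amide_rotatable = FALSE) {
  rot <- find_rotatable_bonds(mol, amide_rotatable)
  keep <- setdiff(seq_len(nrow(mol$bonds)), rot)
  g <- igraph::graph_from_data_frame(
    d = mol$bonds[keep, c("a", "b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol))))
  comp <- igraph::components(g)$membership
  groups <- split(seq_len(n_atoms(mol)), comp)
  groups <- groups[order(vapply(groups, min, integer(1)))]
  lapply(unname(groups), function(idx) {
    fk <- fragment_key(mol, idx)
    list(atom_indices = sort(idx), key = fk$key, map = fk$map,
         n_atoms = length(idx), eligible = length(idx) >= min_atoms)
  })
}

# Induced subgraph of `mol` over atoms `idx` (ascending), as a molgraph.
# Bonds cut at the boundary become implicit hydrogens; tetrahedral parities
# are re-derived for the new neighbor ordering (deleted substituents move to
# the implicit-hydrogen slot at the end of the reference order).
#' @noRd
induced_subgraph_mol <- function(mol, idx) {
  idx <- sort(idx)
  new_idx <- rep(NA_integer_, n_atoms(mol))
  new_idx[idx] <- seq_along(idx)
  atoms <- mol$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  bsel <- which(mol$bonds$a %in% idx & mol$bonds$b %in% idx)
  bonds <- mol$bonds[bsel, , drop = FALSE]
  ncut <- integer(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    nbrs <- neighbors_of(mol, i)
    deleted <- which(!(nbrs %in% idx))
    ncut[k] <- length(deleted)
    p <- atoms$parity[k]
    if (p != 0L) {
      if (length(deleted) == 0L) {
        # unchanged
      } else if (length(deleted) == 1L && atoms$nH[k] == 0L && length(nbrs) == 4L) {
        # one substituent of a fully heavy-substituted center becomes the
        # implicit H: it moves from position `deleted` to the end (position 4)
        if ((4L - deleted) %% 2L == 1L) p <- 3L - p
      } else {
        p <- 0L  # two or more hydrogens: no longer a stereocenter
      }
      atoms$parity[k] <- p
    }
  }
  atoms$nH <- atoms$nH + ncut
  bonds2 <- data.frame(a = new_idx[bonds$a], b = new_idx[bonds$b],
                       order = bonds$order, aromatic = bonds$aromatic)
  molgraph(atoms, bonds2,
           coords = if (!is.null(mol$coords)) mol$coords[idx, , drop = FALSE] else NULL)
}

#' Canonical key of a fragment
#'
#' Canonical SMILES of the induced subgraph over `atom_indices`, with cut
#' bonds replaced by implicit hydrogens (no attachment-point dummies). The
#' returned `map` gives, for each atom position of the canonical ordering,
#' the corresponding parent atom index -- this is what lets stored template
#' coordinates be transferred onto query atoms.
#'
#' For molecules with 3D coordinates (library side) stereo is perceived from
#' the geometry; without coordinates (query side) the declared tetrahedral
#' parities are carried into the key.
#'
#' The canonical ordering is defined as the atom order of the canonical
#' SMILES string itself: the key is re-parsed and matched onto the fragment
#' subgraph by a deterministic colored graph isomorphism (elements, charges,
#' hydrogen counts, normalized bond orders). For symmetric fragments any of
#' the equivalent matches yields a congruent geometry, and the fixed
#' isomorphism search order keeps results bit-reproducible.
#'
#' @param mol a `molgraph`.
#' @param atom_indices atom indices inducing a connected subgraph, or a
#'   fragment match from [fragment_molecule()].
#' @return list with `key` (canonical SMILES), `map` (integer vector: parent
#'   atom index per canonical position), and `n_atoms`.
#' @export
fragment_key <- function(mol, atom_indices) {
  if (is.list(atom_indices)) atom_indices <- atom_indices$atom_indices
  idx <- sort(atom_indices)
  sub <- induced_subgraph_mol(mol, idx)
  if (igraph::count_components(mol_igraph(sub)) != 1L) {
    stop("fragment atoms do not induce a connected subgraph", call. = FALSE)
  }
  mb <- mol_to_molblock(sub, use_coords = !is.null(sub$coords))
  key <- ob_molblock_to_cansmi(mb)
  kg <- parse_smiles(key)
  iso <- .first_isomorphism(kg, sub)
  if (is.null(iso)) {
    # engine round-trip changed perceived valence (rare charged corner):
    # fall back to identity order, which is still a valid template order
    # whenever the atom count survives
    if (n_atoms(kg) != length(idx)) {
      stop("fragment key round trip failed for key ", key, call. = FALSE)
    }
    iso <- seq_along(idx)
  }
  list(key = key, map = idx[iso], n_atoms = length(idx))
}
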