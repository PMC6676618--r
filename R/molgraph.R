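# Molecular graph model: the common currency of all modules.
#
# Heavy atoms only; hydrogens are implicit (per-atom counts) and materialized
# with coordinates only by the coordinate builder. Tetrahedral stereo is kept
# as an MDL-style atom parity (relative to neighbors in ascending atom index,
# implicit hydrogen last); double-bond stereo as explicit (bond, reference
# neighbors, cis/trans) records.

.periodic_symbols <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S","Cl",
  "Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga","Ge",
  "As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd","Ag",
  "Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm","Sm",
  "Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os","Ir",
  "Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn")

#' Construct a molecular graph
#'
#' Low-level constructor used by the SMILES/SDF readers and the fixture
#' generators. Most users will obtain `molgraph` objects from
#' [parse_smiles()] or [read_sdf()].
#'
#' @param atoms data frame with columns `element`, and optionally `charge`,
#'   `aromatic`, `nH`, `parity` (MDL atom parity: 0 none, 1 clockwise,
#'   2 counterclockwise).
#' @param bonds data frame with columns `a`, `b` (1-based atom indices) and
#'   `order` (1, 2, 3; aromatic bonds carry a Kekule order plus an `aromatic`
#'   flag).
#' @param coords optional numeric matrix (n x 3) of coordinates in Angstrom.
#' @param dbstereo optional data frame of declared double-bond stereo:
#'   columns `bond` (row index into `bonds`), `ref_a`, `ref_b` (reference
#'   substituent atom indices) and `config` (`"cis"` or `"trans"`).
#' @param source_id optional identifier (e.g. SD record title).
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds, coords = NULL, dbstereo = NULL, source_id = NULL) {
  n <- nrow(atoms)
  if (n == 0L) stop("molecule has no atoms", call. = FALSE)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$nH)) atoms$nH <- 0L
  if (is.null(atoms$parity)) atoms$parity <- 0L
  bad <- setdiff(unique(atoms$element), .periodic_symbols)
  if (length(bad)) stop("invalid element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (nrow(bonds)) {
    if (is.null(bonds$order)) bonds$order <- 1L
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    if (any(bonds$a == bonds$b)) stop("bond with identical endpoints", call. = FALSE)
    if (any(bonds$a < 1L | bonds$a > n | bonds$b < 1L | bonds$b > n)) {
      stop("bond endpoint out of range", call. = FALSE)
    }
    key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    if (anyDuplicated(key)) stop("duplicate bond", call. = FALSE)
  } else {
    bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0),
                        aromatic = logical(0))
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n, ncol(coords) == 3)
    if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
    dimnames(coords) <- NULL
  }
  mol <- structure(list(
    atoms = atoms, bonds = bonds, coords = coords,
    dbstereo = if (is.null(dbstereo)) {
      data.frame(bond = integer(0), ref_a = integer(0), ref_b = integer(0),
                 config = character(0))
    } else dbstereo,
    source_id = source_id
  ), class = "molgraph")
  mol$bonds$in_ring <- ring_bonds(mol)
  mol$atoms$in_ring <- ring_atoms(mol)
  if (any(mol$bonds$aromatic & !mol$bonds$in_ring)) {
    stop("aromatic bond outside a ring", call. = FALSE)
  }
  mol
}

#' Number of (heavy) atoms in a molecule
#' @param mol a `molgraph`.
#' @return integer count of heavy atoms.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d heavy atoms, %d bonds, %s coordinates%s\n",
              n_atoms(x), nrow(x$bonds),
              if (is.null(x$coords)) "no" else "3D",
              if (is.null(x$source_id)) "" else paste0(" [", x$source_id, "]")))
  invisible(x)
}

# igraph view of the heavy-atom skeleton
#' @noRd
mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("a", "b")] else data.frame(a = integer(0), b = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol)))
  )
}

#' @noRd
ring_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(logical(0))
  g <- mol_igraph(mol)
  br <- igraph::bridges(g)
  res <- rep(TRUE, nrow(mol$bonds))
  res[as.integer(br)] <- FALSE
  res
}

#' @noRd
ring_atoms <- function(mol) {
  inring <- rep(FALSE, n_atoms(mol))
  rb <- mol$bonds[mol$bonds$in_ring %||% ring_bonds(mol), , drop = FALSE]
  inring[c(rb$a, rb$b)] <- TRUE
  inring
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
heavy_degree <- function(mol) {
  tabulate(c(mol$bonds$a, mol$bonds$b), nbins = n_atoms(mol))
}

# neighbors of atom i, ascending
#' @noRd
neighbors_of <- function(mol, i) {
  sort(c(mol$bonds$b[mol$bonds$a == i], mol$bonds$a[mol$bonds$b == i]))
}

#' @noRd
bond_between <- function(mol, i, j) {
  which((mol$bonds$a == i & mol$bonds$b == j) | (mol$bonds$a == j & mol$bonds$b == i))
}

#' Parse a SMILES string into a molecular graph
#'
#' Parsing, kekulization and aromaticity perception are delegated to Open
#' Babel; the result is returned with hydrogens implicit and stereo
#' annotations (tetrahedral parity, declared double-bond configurations)
#' preserved. Multi-component SMILES are rejected.
#'
#' @param smiles a single SMILES string.
#' @param source_id optional identifier attached to the result.
#' @return a `molgraph` without coordinates.
#' @examples
#' m <- parse_smiles("c1ccccc1")
#' n_atoms(m)  # 6
#' @export
parse_smiles <- function(smiles, source_id = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mb <- ob_smiles_to_molblock(smiles)
  pm <- parse_molblock(mb)
  heavy <- which(pm$atoms$element != "H")
  if (length(heavy) == 0L) stop("no heavy atoms in input: ", smiles, call. = FALSE)
  new_idx <- rep(NA_integer_, nrow(pm$atoms))
  new_idx[heavy] <- seq_along(heavy)

  atoms <- pm$atoms[heavy, c("element", "charge", "parity")]
  rownames(atoms) <- NULL
  # hydrogen counts and heavy bonds
  is_h <- pm$atoms$element == "H"
  nH <- integer(length(heavy))
  keep <- logical(nrow(pm$bonds))
  for (k in seq_len(nrow(pm$bonds))) {
    a <- pm$bonds$a[k]; b <- pm$bonds$b[k]
    if (is_h[a] && !is_h[b]) nH[new_idx[b]] <- nH[new_idx[b]] + 1L
    else if (is_h[b] && !is_h[a]) nH[new_idx[a]] <- nH[new_idx[a]] + 1L
    else if (!is_h[a] && !is_h[b]) keep[k] <- TRUE
  }
  atoms$nH <- nH
  bonds <- pm$bonds[keep, , drop = FALSE]
  bonds$a <- new_idx[bonds$a]
  bonds$b <- new_idx[bonds$b]
  rownames(bonds) <- NULL

  # centers with more than one hydrogen cannot be stereocenters
  atoms$parity[atoms$nH > 1L] <- 0L

  # aromatic atoms from the engine's perception
  arom_atoms <- unique(unlist(ob_smarts_match(mb, "[a]")))
  atoms$aromatic <- seq_along(heavy) %in% new_idx[arom_atoms]

  mol <- molgraph(atoms,
                  data.frame(a = bonds$a, b = bonds$b, order = bonds$order,
                             aromatic = logical(nrow(bonds))),
                  source_id = source_id)
  mol$bonds$aromatic <- mol$bonds$in_ring &
    mol$atoms$aromatic[mol$bonds$a] & mol$atoms$aromatic[mol$bonds$b]

  g <- mol_igraph(mol)
  if (igraph::count_components(g) != 1L) {
    stop("multi-component input rejected: ", smiles, call. = FALSE)
  }

  # declared double-bond stereo, perceived from the engine's 2D layout.
  # Bond stereo flag 3 marks an explicitly undeclared stereogenic double bond.
  xy <- as.matrix(pm$atoms[, c("x", "y")])
  db <- which(mol$bonds$order == 2L & !mol$bonds$in_ring & bonds$stereo != 3L)
  recs <- list()
  for (k in db) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    ra <- setdiff(neighbors_of(mol, a), b)
    rb <- setdiff(neighbors_of(mol, b), a)
    if (!length(ra) || !length(rb)) next
    ra <- ra[1]; rb <- rb[1]
    A <- xy[heavy[a], ]; B <- xy[heavy[b], ]
    za <- (B[1] - A[1]) * (xy[heavy[ra], 2] - A[2]) - (B[2] - A[2]) * (xy[heavy[ra], 1] - A[1])
    zb <- (B[1] - A[1]) * (xy[heavy[rb], 2] - A[2]) - (B[2] - A[2]) * (xy[heavy[rb], 1] - A[1])
    if (abs(za) < 1e-6 || abs(zb) < 1e-6) next
    recs[[length(recs) + 1L]] <- data.frame(
      bond = k, ref_a = ra, ref_b = rb,
      config = if (sign(za) == sign(zb)) "cis" else "trans")
  }
  if (length(recs)) mol$dbstereo <- do.call(rbind, recs)
  # canonical form of the input, cached: a 0D molblock cannot express declared
  # double-bond configurations, so the coordinate-free canonicalization path
  # would silently drop them
  mol$cansmi <- {
    out <- ob_convert("SMI", "CAN", smiles)
    strsplit(out, "[ \t\n]", perl = TRUE)[[1]][1]
  }
  mol
}

# molgraph -> V2000 molblock. use_coords writes a 3D block (atom parities are
# then omitted: stereo lives in the geometry); otherwise a 0D block carrying
# parities. with_h materializes no hydrogens -- builder output molecules carry
# explicit H as ordinary atoms already.
#' @noRd
mol_to_molblock <- function(mol, use_coords = !is.null(mol$coords), title = "") {
  if (use_coords && is.null(mol$coords)) stop("molecule has no coordinates", call. = FALSE)
  make_molblock(
    elements = mol$atoms$element,
    bonds = mol$bonds,
    coords = if (use_coords) mol$coords else NULL,
    charges = mol$atoms$charge,
    parity = if (use_coords) NULL else mol$atoms$parity,
    title = title %||% ""
  )
}

#' Canonical SMILES of a molecule
#'
#' A single canonicalization engine (Open Babel) is used throughout the
#' package, so fragment keys computed at library-build time and at query time
#' always live in the same dialect. For molecules with coordinates, stereo is
#' perceived from 3D; otherwise stored stereo annotations are used.
#'
#' @param mol a `molgraph`, or a SMILES string (parsed first).
#' @return canonical SMILES string.
#' @examples
#' canonical_smiles("OCC") == canonical_smiles("CCO")
#' @export
canonical_smiles <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  if (is.null(mol$coords) && !is.null(mol$cansmi)) return(mol$cansmi)
  ob_molblock_to_cansmi(mol_to_molblock(mol))
}

#' Hybridization class of an atom
#'
#' Pure graph rule: `sp` for atoms with a triple bond or two or more double
#' bonds, `sp2` for aromatic atoms or atoms with exactly one double bond,
#' `sp3` otherwise for common organic elements, `other` for anything else.
#' Coordinates never enter.
#'
#' @param mol a `molgraph`.
#' @param atom_idx atom index (1-based); vectorized.
#' @return character vector in `c("sp","sp2","sp3","other")`.
#' @export
perceive_hybridization <- function(mol, atom_idx = seq_len(n_atoms(mol))) {
  organic <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "As", "Se", "Br", "I")
  vapply(atom_idx, function(i) {
    ord <- c(mol$bonds$order[mol$bonds$a == i], mol$bonds$order[mol$bonds$b == i])
    if (any(ord == 3L) || sum(ord == 2L) >= 2L) return("sp")
    if (mol$atoms$aromatic[i] || sum(ord == 2L) == 1L) return("sp2")
    if (mol$atoms$element[i] %in% organic) return("sp3")
    "other"
  }, character(1))
}

#' InChIKey of molecules or SMILES strings
#'
#' Standard 27-character InChIKeys, generated by the `obabel` command-line
#' tool. For molecules carrying 3D coordinates stereochemistry is perceived
#' from the geometry; graphs without coordinates use their declared stereo.
#' Conversion failures yield `NA` (treated as stereo failures downstream).
#'
#' @param x a character vector of SMILES, a `molgraph`, or a list of
#'   `molgraph` objects.
#' @return character vector of InChIKeys (`NA` on failure).
#' @export
inchikey <- function(x) {
  if (is.character(x)) return(ob_inchikey(x, "smi"))
  if (inherits(x, "molgraph")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "molgraph")))
  path <- tempfile(fileext = ".sdf")
  on.exit(unlink(path), add = TRUE)
  write_sdf(x, path)
  ob_inchikey(path, "sdf")
}

#' Read molecules from an SD file
#'
#' @param path path to an SD/MOL (V2000) file.
#' @param perceive_aromaticity run the engine's aromaticity perception on each
#'   record (needed when records are compared across kekulizations).
#' @return a list of `molgraph` objects; explicit hydrogens are folded into
#'   per-atom counts, coordinates are kept.
#' @export
read_sdf <- function(path, perceive_aromaticity = TRUE) {
  records <- split_sdf_records(readLines(path, warn = FALSE))
  lapply(records, function(rec) {
    mol_from_molblock(rec$molblock, perceive_aromaticity = perceive_aromaticity)
  })
}

#' @noRd
mol_from_molblock <- function(lines, perceive_aromaticity = TRUE, source_id = NULL) {
  pm <- parse_molblock(lines)
  heavy <- which(pm$atoms$element != "H")
  if (!length(heavy)) stop("record without heavy atoms", call. = FALSE)
  new_idx <- rep(NA_integer_, nrow(pm$atoms))
  new_idx[heavy] <- seq_along(heavy)
  atoms <- pm$atoms[heavy, c("element", "charge", "parity")]
  rownames(atoms) <- NULL
  is_h <- pm$atoms$element == "H"
  nH <- integer(length(heavy))
  keep <- logical(nrow(pm$bonds))
  for (k in seq_len(nrow(pm$bonds))) {
    a <- pm$bonds$a[k]; b <- pm$bonds$b[k]
    if (is_h[a] && !is_h[b]) nH[new_idx[b]] <- nH[new_idx[b]] + 1L
    else if (is_h[b] && !is_h[a]) nH[new_idx[a]] <- nH[new_idx[a]] + 1L
    else if (!is_h[a] && !is_h[b]) keep[k] <- TRUE
  }
  atoms$nH <- nH
  bonds <- pm$bonds[keep, c("a", "b", "order")]
  bonds$a <- new_idx[bonds$a]
  bonds$b <- new_idx[bonds$b]
  rownames(bonds) <- NULL
  bonds$aromatic <- FALSE
  coords <- as.matrix(pm$atoms[heavy, c("x", "y", "z")])
  has_coords <- any(abs(coords) > 1e-8)
  mol <- molgraph(atoms, bonds, coords = if (has_coords) coords else NULL,
                  source_id = source_id %||%
                    (if (nzchar(trimws(pm$title))) trimws(pm$title) else NULL))
  if (perceive_aromaticity && nrow(mol$bonds)) {
    mb <- if (is.character(lines) && length(lines) > 1L) paste(lines, collapse = "\n") else lines
    arom <- unique(unlist(ob_smarts_match(mb, "[a]")))
    mol$atoms$aromatic <- seq_along(heavy) %in% new_idx[arom]
    mol$bonds$aromatic <- mol$bonds$in_ring &
      mol$atoms$aromatic[mol$bonds$a] & mol$atoms$aromatic[mol$bonds$b]
  }
  mol
}

#' Write molecules to an SD file
#'
#' Output is deterministic (no timestamps): identical inputs produce
#' byte-identical files.
#'
#' @param mols a `molgraph` or list of them (with or without coordinates).
#' @param path output file path.
#' @param names optional record titles; defaults to each molecule's
#'   `source_id`.
#' @param data optional list (one element per molecule) of named character
#'   vectors written as SD data fields.
#' @return `invisible(path)`.
#' @export
write_sdf <- function(mols, path, names = NULL, data = NULL) {
  if (inherits(mols, "molgraph")) mols <- list(mols)
  out <- character(0)
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    title <- if (!is.null(names)) names[i] else mol$source_id %||% ""
    mb <- mol_to_molblock(mol, use_coords = !is.null(mol$coords), title = title)
    out <- c(out, sub("\n$", "", mb))
    if (!is.null(data) && length(data) >= i && length(data[[i]])) {
      d <- data[[i]]
      for (tag in names(d)) out <- c(out, sprintf("> <%s>", tag), d[[tag]], "")
    }
    out <- c(out, "$$$$")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
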