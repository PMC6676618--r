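# The coordinate generator: depth-first traversal of the query molecule,
# rigid placement of matched fragment templates, rule-based one-by-one
# placement of remaining atoms from hybridization geometry, ring-closure
# auditing, hydrogen placement, and stereochemistry enforcement.
#
# Determinism conventions: the first atom sits at the origin, the first bond
# direction is +z and the first perpendicular reference +x; DFS starts at
# atom 1 and visits neighbors in ascending input index; free torsions are
# fixed anti (180 degrees) against the highest-index placed reference.

.base_directions <- function(n_positions) {
  c13 <- -1 / 3; s13 <- 2 * sqrt(2) / 3
  switch(as.character(n_positions),
    "1" = ,
    "2" = rbind(c(0, 0, 1), c(0, 0, -1)),
    "3" = rbind(c(0, 0, 1),
                c(sin(.rad(120)), 0, cos(.rad(120))),
                c(-sin(.rad(120)), 0, cos(.rad(120)))),
    "4" = rbind(c(0, 0, 1),
                c(s13, 0, c13),
                c(s13 * cos(.rad(120)), s13 * sin(.rad(120)), c13),
                c(s13 * cos(.rad(240)), s13 * sin(.rad(240)), c13)),
    rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  )
}

# a deterministic unit vector perpendicular to u
.any_perp <- function(u) {
  p <- cross3(u, c(1, 0, 0))
  if (vnorm(p) < 1e-6) p <- cross3(u, c(0, 1, 0))
  unit(p)
}

# Idealized directions for the unfilled valences of an atom, given the
# geometry class, already-present neighbor unit directions U (rows), the
# total number of sigma positions wanted, and an optional torsion reference:
# ref_dir is the unit vector from the (single) existing neighbor toward its
# own reference substituent; the first returned direction is then anti to it.
#' @noRd
.open_directions <- function(geom, U, n_slots, ref_dir = NULL) {
  n_pos <- switch(geom, sp = 2L, sp2 = 3L, sp3 = 4L, 4L)
  n_pos <- max(n_pos, n_slots)
  k <- if (is.null(U)) 0L else nrow(U)
  n_open <- max(0L, min(n_slots, n_pos) - k)
  if (n_open == 0L) return(matrix(numeric(0), 0, 3))

  if (k == 0L) {
    return(.base_directions(n_pos)[seq_len(n_open), , drop = FALSE])
  }

  if (n_pos <= 2L) {                       # sp: one partner, anti
    return(matrix(-U[1, ], 1, 3))
  }

  theta <- if (n_pos == 3L) .rad(120) else .rad(109.4712206)

  if (k == 1L) {
    u1 <- unit(U[1, ])
    # azimuth reference: anti to ref_dir if given, else a fixed perpendicular
    w0 <- if (!is.null(ref_dir)) {
      perp <- ref_dir - sum(ref_dir * u1) * u1
      if (vnorm(perp) < 1e-6) .any_perp(u1) else -unit(perp)
    } else .any_perp(u1)
    n_az <- n_pos - 1L
    az <- 2 * pi * (seq_len(n_az) - 1L) / n_az
    dirs <- t(vapply(az, function(phi) {
      w <- rotation_about(u1, phi) %*% w0
      cos(theta) * u1 + sin(theta) * as.numeric(w)
    }, numeric(3)))
    return(dirs[seq_len(n_open), , drop = FALSE])
  }

  if (k >= n_pos - 1L) {                   # one position left: opposite the sum
    s <- colSums(U)
    v <- if (vnorm(s) < 1e-6) .any_perp(U[1, ]) else -unit(s)
    if (n_pos == 4L && k == 3L) {
      # a ring-closure neighbor can leave the three existing directions near
      # coplanar with their negated sum; a flat center is stereochemically
      # ambiguous, so demand a real out-of-plane component
      n <- cross3(U[2, ] - U[1, ], U[3, ] - U[1, ])
      if (vnorm(n) > 1e-6) {
        n <- unit(n)
        if (abs(sum(n * v)) < 0.5) {
          v <- if (sum(n * v) >= 0) n else -n
        }
      }
    }
    return(matrix(v, 1, 3))
  }

  # sp3 with two placed neighbors: the two remaining tetrahedral positions
  u1 <- unit(U[1, ]); u2 <- unit(U[2, ])
  g <- sum(u1 * u2)
  a <- cos(theta) / (1 + g)
  b2 <- (1 - a^2 * 2 * (1 + g)) / max(1e-12, 1 - g^2)
  axis <- cross3(u1, u2)
  if (b2 <= 0 || vnorm(axis) < 1e-6) {
    v <- -unit(u1 + u2)
    return(matrix(v, 1, 3)[seq_len(min(1L, n_open)), , drop = FALSE])
  }
  b <- sqrt(b2)
  dirs <- rbind(unit(a * (u1 + u2) + b * unit(axis)),
                unit(a * (u1 + u2) - b * unit(axis)))
  dirs[seq_len(n_open), , drop = FALSE]
}

# ---------------------------------------------------------------------------

#' @noRd
new_working_molecule <- function(mol) {
  n <- n_atoms(mol)
  structure(list(
    mol = mol,
    coords = matrix(NA_real_, n, 3),
    placed = logical(n),
    provenance = rep(NA_character_, n),
    used = logical(nrow(mol$bonds)),
    hyb = perceive_hybridization(mol),
    h_owner = integer(0),
    h_coords = matrix(numeric(0), 0, 3),
    corrections = 0L,
    log = character(0)
  ), class = "working_molecule")
}

#' Open valence directions of a placed atom
#'
#' Idealized unit directions for the unfilled valences of atom `atom_idx`
#' given its hybridization and already-placed neighbors: sp completes the
#' line (180 deg), sp2 the trigonal plane (120 deg), sp3 the tetrahedron
#' (109.47 deg). With a single placed neighbor the free azimuth is anchored so
#' the first direction is anti (180 deg torsion) to the neighbor's own
#' highest-index placed substituent.
#'
#' @param work a working molecule (see [generate_coordinates()]).
#' @param atom_idx atom index; must be placed.
#' @return matrix of unit direction row vectors (possibly 0 rows).
#' @export
open_valence_directions <- function(work, atom_idx) {
  if (!work$placed[atom_idx]) stop("atom ", atom_idx, " is not placed", call. = FALSE)
  mol <- work$mol
  nbrs <- neighbors_of(mol, atom_idx)
  placed_nbrs <- nbrs[work$placed[nbrs]]
  own_h <- which(work$h_owner == atom_idx)
  U <- NULL
  if (length(placed_nbrs) || length(own_h)) {
    U <- rbind(
      if (length(placed_nbrs))
        t(vapply(placed_nbrs, function(j) unit(work$coords[j, ] - work$coords[atom_idx, ]),
                 numeric(3))),
      if (length(own_h))
        t(vapply(own_h, function(h) unit(work$h_coords[h, ] - work$coords[atom_idx, ]),
                 numeric(3)))
    )
  }
  ref_dir <- NULL
  if (length(placed_nbrs) == 1L && length(own_h) == 0L) {
    j <- placed_nbrs[1]
    refs <- setdiff(neighbors_of(mol, j), atom_idx)
    refs <- refs[work$placed[refs]]
    if (length(refs)) {
      h <- max(refs)
      ref_dir <- unit(work$coords[h, ] - work$coords[j, ])
    }
  }
  n_slots <- length(nbrs) + mol$atoms$nH[atom_idx]
  .open_directions(work$hyb[atom_idx], U, n_slots, ref_dir)
}

#' Place a single atom by valence geometry rules
#'
#' The atom goes at the ideal bond length along the first open valence
#' direction of its placed neighbor `parent`; with a placed reference three
#' bonds back, that direction is the anti (180 deg) torsion. The very first
#' atom of a molecule sits at the origin.
#'
#' @param work a working molecule.
#' @param atom_idx atom to place.
#' @param parent placed neighbor anchoring the new atom, or `NULL` for the
#'   first atom.
#' @return the updated working molecule.
#' @export
place_atom_rule_based <- function(work, atom_idx, parent = NULL) {
  if (work$placed[atom_idx]) stop("atom ", atom_idx, " already placed", call. = FALSE)
  if (is.null(parent)) {
    work$coords[atom_idx, ] <- c(0, 0, 0)
  } else {
    dirs <- open_valence_directions(work, parent)
    if (nrow(dirs) == 0L) {
      # valence bookkeeping exhausted (hypervalent corner): fall back opposite
      # the mean of existing neighbors and log it
      nb <- neighbors_of(work$mol, parent)
      nb <- nb[work$placed[nb]]
      s <- colSums(work$coords[nb, , drop = FALSE]) / length(nb) - work$coords[parent, ]
      dirs <- matrix(if (vnorm(s) < 1e-6) c(0, 0, 1) else -unit(s), 1, 3)
      work$log <- c(work$log, sprintf("no open valence on atom %d; fallback direction used", parent))
    }
    k <- bond_between(work$mol, parent, atom_idx)
    L <- ideal_length_for_bond(work$mol, k)
    work$coords[atom_idx, ] <- work$coords[parent, ] + L * dirs[1, ]
    work$used[k] <- TRUE
  }
  work$placed[atom_idx] <- TRUE
  work$provenance[atom_idx] <- "rule"
  work
}

#' Rigidly place a fragment template
#'
#' The template is transformed by rotation + translation only (all internal
#' distances preserved): the anchor query atom lands at the ideal bond length
#' along an open valence direction of the placed anchor atom, the cut-bond
#' direction of the template points back along that bond, and the residual
#' spin about the bond axis is fixed by the anti-torsion rule. Without an
#' anchor (first placement) the template is seated in the canonical frame
#' (seat atom at the origin, first bond +z, first perpendicular +x).
#'
#' @param work a working molecule.
#' @param frag list with `coords` (template geometry, one row per mapped
#'   atom) and optionally `label` (provenance tag).
#' @param mapping integer vector: query atom index per template row.
#' @param anchor `list(placed = <placed atom>, query = <mapped atom>)`, or
#'   `NULL` for the first placement.
#' @param at seat atom (mapped query atom) used for the anchorless frame;
#'   defaults to the first mapped atom.
#' @return the updated working molecule.
#' @export
place_fragment <- function(work, frag, mapping, anchor = NULL, at = NULL) {
  mol <- work$mol
  X <- frag$coords
  stopifnot(nrow(X) == length(mapping))
  if (any(work$placed[mapping])) stop("fragment overlaps placed atoms", call. = FALSE)
  label <- frag$label %||% "fragment_exact"
  tpos <- function(q) match(q, mapping)

  if (is.null(anchor)) {
    q0 <- at %||% mapping[1]
    i0 <- tpos(q0)
    Xc <- sweep(X, 2, X[i0, ])
    nb <- intersect(neighbors_of(mol, q0), mapping)
    R <- diag(3)
    if (length(nb)) {
      v1 <- Xc[tpos(nb[1]), ]
      R <- rotation_between(v1, c(0, 0, 1))
      Xr <- Xc %*% t(R)
      # spin about z: put the next reference into the +x half-plane
      ref <- if (length(nb) >= 2L) Xr[tpos(nb[2]), ] else {
        nb2 <- setdiff(intersect(unlist(lapply(nb, neighbors_of, mol = mol)), mapping), q0)
        if (length(nb2)) Xr[tpos(sort(nb2)[1]), ] else NULL
      }
      if (!is.null(ref)) {
        perp <- ref - c(0, 0, sum(ref * c(0, 0, 1)))
        if (vnorm(perp) > 1e-6) {
          phi <- atan2(perp[2], perp[1])
          R <- rotation_about(c(0, 0, 1), -phi) %*% R
        }
      }
      Xc <- Xc %*% t(R)
    }
    new_xyz <- Xc
  } else {
    p <- anchor$placed; q0 <- anchor$query
    stopifnot(work$placed[p], q0 %in% mapping)
    dirs <- open_valence_directions(work, p)
    if (nrow(dirs) == 0L) {
      stop("anchor atom ", p, " has no open valence direction", call. = FALSE)
    }
    d <- dirs[1, ]
    kb <- bond_between(mol, p, q0)
    L <- ideal_length_for_bond(mol, kb)
    t0 <- work$coords[p, ] + L * d
    i0 <- tpos(q0)

    # cut-bond direction of the template at q0
    nb_t <- intersect(neighbors_of(mol, q0), mapping)
    Ut <- if (length(nb_t)) {
      t(vapply(nb_t, function(q) unit(X[tpos(q), ] - X[i0, ]), numeric(3)))
    } else NULL
    n_slots <- length(neighbors_of(mol, q0)) + mol$atoms$nH[q0]
    v_open <- .open_directions(work$hyb[q0], Ut, n_slots, NULL)
    v0 <- if (nrow(v_open)) v_open[1, ] else c(0, 0, 1)
    R <- rotation_between(v0, -d)
    Xr <- sweep(X, 2, X[i0, ]) %*% t(R)

    # spin about the new bond axis: anti torsion ref_p - p - q0 - ref_q
    refs_p <- setdiff(neighbors_of(mol, p), q0)
    refs_p <- refs_p[work$placed[refs_p]]
    ref_q <- sort(nb_t)
    if (length(refs_p) && length(ref_q)) {
      rp <- max(refs_p)
      axis <- unit(t0 - work$coords[p, ])
      cur <- dihedral(work$coords[rp, ], work$coords[p, ], t0, t0 + Xr[tpos(ref_q[1]), ])
      for (phi in .rad(c(180 - cur, -(180 - cur)))) {
        Xtry <- Xr %*% t(rotation_about(axis, phi))
        tau <- dihedral(work$coords[rp, ], work$coords[p, ], t0, t0 + Xtry[tpos(ref_q[1]), ])
        if (circular_diff(tau, 180) < 1e-6) { Xr <- Xtry; break }
      }
    }
    new_xyz <- sweep(Xr, 2, t0, `+`)
    work$used[kb] <- TRUE
  }

  work$coords[mapping, ] <- new_xyz
  work$placed[mapping] <- TRUE
  work$provenance[mapping] <- label
  intra <- which(mol$bonds$a %in% mapping & mol$bonds$b %in% mapping)
  work$used[intra] <- TRUE
  work
}

#' Audit ring-closure bonds
#'
#' Bonds of the query graph that were never traversed during placement (ring
#' closures across fragment or rule boundaries) are measured against their
#' ideal length; closures longer than `factor` times ideal are flagged --
#' never fixed (that is a post-optimizer's job).
#'
#' @param work a working molecule with all heavy atoms placed.
#' @param factor flag threshold as a multiple of the ideal length.
#' @return data frame with columns `a`, `b`, `actual`, `ideal` (0 rows when
#'   every closure is sane).
#' @export
close_rings <- function(work, factor = 1.5) {
  stopifnot(all(work$placed))
  out <- data.frame(a = integer(0), b = integer(0), actual = numeric(0), ideal = numeric(0))
  for (k in which(!work$used)) {
    a <- work$mol$bonds$a[k]; b <- work$mol$bonds$b[k]
    actual <- vnorm(work$coords[a, ] - work$coords[b, ])
    ideal <- ideal_length_for_bond(work$mol, k)
    if (actual > factor * ideal) {
      out <- rbind(out, data.frame(a = a, b = b, actual = actual, ideal = ideal))
    }
  }
  out
}

#' Materialize hydrogens
#'
#' Hydrogens are placed on the remaining open valence directions of each
#' heavy atom at the ideal X-H length, after all heavy atoms are committed.
#'
#' @param work a working molecule with all heavy atoms placed.
#' @return the updated working molecule (hydrogen coordinates filled).
#' @export
place_hydrogens <- function(work) {
  stopifnot(all(work$placed))
  mol <- work$mol
  for (i in seq_len(n_atoms(mol))) {
    nh <- mol$atoms$nH[i]
    if (nh == 0L) next
    dirs <- open_valence_directions(work, i)
    if (nrow(dirs) < nh) {
      extra <- matrix(rep(-unit(colSums(rbind(dirs, c(0, 0, 1)))), nh - nrow(dirs)),
                      ncol = 3, byrow = TRUE)
      dirs <- rbind(dirs, extra)
      work$log <- c(work$log, sprintf("hydrogen overflow on atom %d", i))
    }
    L <- ideal_bond_length(mol$atoms$element[i], "H", 1L)
    for (m in seq_len(nh)) {
      work$h_owner <- c(work$h_owner, i)
      work$h_coords <- rbind(work$h_coords, work$coords[i, ] + L * dirs[m, ])
    }
  }
  work
}

# combined heavy+hydrogen view used by stereo enforcement:
# atoms 1..n are heavy, n+1..n+nh hydrogens in placement order
#' @noRd
.combined_view <- function(work) {
  n <- n_atoms(work$mol)
  nh <- length(work$h_owner)
  xyz <- rbind(work$coords, work$h_coords)
  bonds <- rbind(work$mol$bonds[, c("a", "b")],
                 data.frame(a = work$h_owner, b = n + seq_len(nh)))
  adj <- vector("list", n + nh)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a[k]]] <- c(adj[[bonds$a[k]]], bonds$b[k])
    adj[[bonds$b[k]]] <- c(adj[[bonds$b[k]]], bonds$a[k])
  }
  list(xyz = xyz, adj = lapply(adj, sort), n_heavy = n)
}

# connected component containing `start` in the combined graph with `drop`
# vertices removed
#' @noRd
.branch_atoms <- function(adj, start, drop) {
  seen <- c(drop, start)
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nxt <- setdiff(adj[[v]], seen)
    seen <- c(seen, nxt)
    queue <- c(queue, nxt)
  }
  setdiff(seen, drop)
}

#' @noRd
.geometric_parity <- function(xyz, nbrs) {
  # MDL convention: neighbors in ascending atom number (hydrogen last);
  # parity 2 (counterclockwise) iff det(r1-r4, r2-r4, r3-r4) > 0
  r <- xyz[nbrs, , drop = FALSE]
  v <- sweep(r[1:3, , drop = FALSE], 2, r[4, ])
  if (det(v) > 0) 2L else 1L
}

#' Enforce declared stereochemistry
#'
#' For each declared tetrahedral center the geometric parity (sign of the
#' signed volume over the ordered substituents) is compared with the declared
#' parity; on mismatch the two substituent branches with the fewest atoms
#' (lying in distinct components of the graph minus the center) are swapped by
#' rigid rotation about the center. Declared double-bond configurations are
#' checked against the built torsion and fixed by a 180-degree rotation of the
#' smaller side about the bond axis. Ring-locked centers that cannot be
#' corrected are logged.
#'
#' @param work a working molecule with heavy atoms and hydrogens placed.
#' @return the updated working molecule (`$corrections` counts changes).
#' @export
enforce_stereo <- function(work) {
  mol <- work$mol
  cv <- .combined_view(work)

  commit <- function() {
    work$coords <<- cv$xyz[seq_len(cv$n_heavy), , drop = FALSE]
    if (length(work$h_owner)) {
      work$h_coords <<- cv$xyz[cv$n_heavy + seq_along(work$h_owner), , drop = FALSE]
    }
  }

  # normalized signed volume over the unit substituent directions: the sign is
  # the parity, a small magnitude marks a flattened (ambiguous) center
  norm_det <- function(c0, nbrs) {
    u <- t(vapply(nbrs, function(v) unit(cv$xyz[v, ] - c0), numeric(3)))
    det(sweep(u[1:3, , drop = FALSE], 2, u[4, ]))
  }

  for (i in which(mol$atoms$parity != 0L)) {
    nbrs <- cv$adj[[i]]
    if (length(nbrs) < 4L) next
    nbrs <- nbrs[order(nbrs)][1:4]
    c0 <- cv$xyz[i, ]
    D <- norm_det(c0, nbrs)
    want <- if (mol$atoms$parity[i] == 2L) 1 else -1
    mismatched <- sign(D) != want
    degenerate <- abs(D) < 0.3
    if (!mismatched && !degenerate) next

    branches <- lapply(nbrs, function(nb) .branch_atoms(cv$adj, nb, i))
    ids <- vapply(branches, function(br) min(br), numeric(1))
    sizes <- vapply(branches, length, integer(1))
    swappable <- vapply(seq_along(nbrs), function(j) sum(ids == ids[j]) == 1L, logical(1))

    # repair by moving one detachable branch onto a clean tetrahedral
    # position: used for flattened centers and for mismatched centers where
    # no two-branch swap is available (e.g. a ring-fusion center whose only
    # detachable substituent is its hydrogen)
    repair_one <- function(j) {
      m <- nbrs[j]
      others <- nbrs[-j]
      U <- t(vapply(others, function(v) unit(cv$xyz[v, ] - c0), numeric(3)))
      v <- -colSums(U)
      n <- cross3(U[2, ] - U[1, ], U[3, ] - U[1, ])
      if (vnorm(n) > 1e-6) {
        n <- unit(n)
        v <- if (vnorm(v) < 0.3 || abs(sum(n * unit(v))) < 0.5) n else unit(v)
      } else {
        v <- if (vnorm(v) < 1e-6) .any_perp(U[1, ]) else unit(v)
      }
      test <- function(dir) {
        u4 <- t(vapply(nbrs, function(vv) {
          if (vv == m) dir else unit(cv$xyz[vv, ] - c0)
        }, numeric(3)))
        det(sweep(u4[1:3, , drop = FALSE], 2, u4[4, ]))
      }
      if (sign(test(v)) != want) v <- -v
      R <- rotation_between(unit(cv$xyz[m, ] - c0), v)
      for (vv in branches[[j]]) cv$xyz[vv, ] <<- c0 + as.numeric(R %*% (cv$xyz[vv, ] - c0))
      if (mismatched) work$corrections <<- work$corrections + 1L
      work$log <<- c(work$log, sprintf("stereocenter %d re-pyramidalized%s", i,
                                       if (mismatched) " (parity corrected)" else ""))
    }

    # preferred fix for a clean-geometry mismatch: swap the two smallest
    # detachable substituent branches by rigid rotation about the center
    pick <- integer(0)
    if (mismatched && !degenerate) {
      ord <- order(sizes, nbrs)
      for (j in ord) {
        if (!swappable[j]) next
        if (!length(pick)) pick <- j
        else if (ids[j] != ids[pick[1]]) { pick <- c(pick, j); break }
      }
    }

    if (length(pick) >= 2L) {
      a <- nbrs[pick[1]]; b <- nbrs[pick[2]]
      ua <- unit(cv$xyz[a, ] - c0); ub <- unit(cv$xyz[b, ] - c0)
      Rab <- rotation_between(ua, ub); Rba <- rotation_between(ub, ua)
      for (v in branches[[pick[1]]]) cv$xyz[v, ] <- c0 + as.numeric(Rab %*% (cv$xyz[v, ] - c0))
      for (v in branches[[pick[2]]]) cv$xyz[v, ] <- c0 + as.numeric(Rba %*% (cv$xyz[v, ] - c0))
      work$corrections <- work$corrections + 1L
      work$log <- c(work$log, sprintf("inverted stereocenter %d corrected (swapped branches at atoms %d/%d)", i, a, b))
    } else if (any(swappable)) {
      cand <- which(swappable)
      repair_one(cand[order(sizes[cand], nbrs[cand])][1])
    } else {
      work$log <- c(work$log, sprintf("stereocenter %d is ring-locked; not corrected", i))
      next
    }
    if (sign(norm_det(c0, nbrs)) != want) {
      work$log <- c(work$log, sprintf("stereocenter %d still mismatched after correction", i))
    }
  }

  if (nrow(mol$dbstereo)) {
    for (r in seq_len(nrow(mol$dbstereo))) {
      k <- mol$dbstereo$bond[r]
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
      ra <- mol$dbstereo$ref_a[r]; rb <- mol$dbstereo$ref_b[r]
      tau <- dihedral(cv$xyz[ra, ], cv$xyz[a, ], cv$xyz[b, ], cv$xyz[rb, ])
      geo <- if (abs(tau) > 90) "trans" else "cis"
      if (geo == mol$dbstereo$config[r]) next
      if (mol$bonds$in_ring[k]) {
        work$log <- c(work$log, sprintf("double bond %d-%d is ring-locked; not corrected", a, b))
        next
      }
      side_b <- .branch_atoms(cv$adj, b, a)
      side_a <- .branch_atoms(cv$adj, a, b)
      rot_side <- if (length(side_b) <= length(side_a)) side_b else side_a
      axis <- cv$xyz[b, ] - cv$xyz[a, ]
      R <- rotation_about(axis, pi)
      o <- cv$xyz[a, ]
      for (v in rot_side) cv$xyz[v, ] <- o + as.numeric(R %*% (cv$xyz[v, ] - o))
      work$corrections <- work$corrections + 1L
      work$log <- c(work$log, sprintf("double bond %d-%d rotated to declared %s", a, b, mol$dbstereo$config[r]))
    }
  }

  commit()
  work
}

# ---------------------------------------------------------------------------

#' Generate 3D coordinates for a molecule
#'
#' Orchestrates the full pipeline: fragmentation at rotatable bonds, per
#' fragment lookup (exact key against the library, then generic ring
#' templates), depth-first placement (whole fragments rigidly, remaining
#' atoms one by one from valence geometry rules), ring-closure auditing,
#' hydrogen placement, and stereo enforcement. Deterministic: identical input
#' and library give bit-identical output.
#'
#' @param smiles a SMILES string (or an already-parsed `molgraph` without
#'   coordinates).
#' @param lib a `fragment_library`, or `NULL` for the pure rule path.
#' @param templates generic ring templates, or `NULL` to disable the tier.
#' @param min_atoms,amide_rotatable fragmentation settings (must match the
#'   library's).
#' @return list with `mol` (a `molgraph` with coordinates; hydrogens explicit)
#'   and `report` (a `build_report`: atom provenance, long ring closures,
#'   stereo corrections, log).
#' @examples
#' \dontrun{
#' lib <- build_library(build_fixture_corpus())
#' res <- generate_coordinates("c1ccccc1-c1ccccc1", lib)
#' res$report
#' }
#' @export
generate_coordinates <- function(smiles, lib = NULL,
                                 templates = generic_ring_templates(),
                                 min_atoms = 5L, amide_rotatable = FALSE) {
  mol <- if (inherits(smiles, "molgraph")) smiles else parse_smiles(smiles, source_id = smiles)
  frags <- fragment_molecule(mol, min_atoms = min_atoms, amide_rotatable = amide_rotatable)

  # resolve each fragment against the two lookup tiers
  group_of <- integer(n_atoms(mol))
  groups <- list()
  for (f in frags) {
    placed_group <- NULL
    if (f$eligible && !is.null(lib)) {
      rec <- lookup_exact(lib, f$key)
      if (!is.null(rec) && rec$n_atoms == f$n_atoms &&
          identical(rec$elements, mol$atoms$element[f$map])) {
        placed_group <- list(atoms = f$map, X = rec$coords, label = "fragment_exact")
      }
    }
    if (is.null(placed_group) && f$eligible && !is.null(templates) && length(templates)) {
      sub <- induced_subgraph_mol(mol, f$atom_indices)
      hit <- lookup_generic_ring(templates, sub)
      if (!is.null(hit)) {
        placed_group <- list(atoms = sort(f$atom_indices)[hit$mapping],
                             X = hit$template$coords, label = "fragment_generic")
      }
    }
    if (!is.null(placed_group)) {
      groups[[length(groups) + 1L]] <- placed_group
      group_of[placed_group$atoms] <- length(groups)
    }
  }

  work <- new_working_molecule(mol)

  # iterative DFS from atom 1, neighbors in ascending index
  visited <- logical(n_atoms(mol))
  stack <- list(list(atom = 1L, parent = NULL))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- fr$atom
    if (visited[i]) next
    visited[i] <- TRUE
    if (!work$placed[i]) {
      g <- group_of[i]
      if (g > 0L) {
        grp <- groups[[g]]
        anchor <- if (!is.null(fr$parent)) list(placed = fr$parent, query = i) else NULL
        work <- place_fragment(work, list(coords = grp$X, label = grp$label),
                               mapping = grp$atoms, anchor = anchor, at = i)
      } else {
        work <- place_atom_rule_based(work, i, fr$parent)
      }
    }
    for (nb in rev(setdiff(neighbors_of(mol, i), which(visited)))) {
      stack[[length(stack) + 1L]] <- list(atom = nb, parent = i)
    }
  }

  long_closures <- close_rings(work)
  work <- place_hydrogens(work)
  work <- enforce_stereo(work)

  prov <- work$provenance
  report <- structure(list(
    n_fragment_atoms = sum(prov %in% c("fragment_exact", "fragment_generic")),
    n_rule_atoms = sum(prov == "rule"),
    provenance = prov,
    long_closure_bonds = long_closures,
    stereo_corrections = work$corrections,
    log = work$log
  ), class = "build_report")

  nh <- length(work$h_owner)
  out <- molgraph(
    atoms = data.frame(
      element = c(mol$atoms$element, rep("H", nh)),
      charge = c(mol$atoms$charge, integer(nh)),
      aromatic = c(mol$atoms$aromatic, logical(nh)),
      nH = 0L,
      parity = 0L),
    bonds = rbind(mol$bonds[, c("a", "b", "order", "aromatic")],
                  if (nh) data.frame(a = work$h_owner, b = n_atoms(mol) + seq_len(nh),
                                     order = 1L, aromatic = FALSE)),
    coords = rbind(work$coords, work$h_coords),
    source_id = mol$source_id
  )
  list(mol = out, report = report)
}

#' @export
print.build_report <- function(x, ...) {
  cat(sprintf("<build_report> %d fragment atoms, %d rule atoms, %d long closure(s), %d stereo correction(s)\n",
              x$n_fragment_atoms, x$n_rule_atoms, nrow(x$long_closure_bonds),
              x$stereo_corrections))
  invisible(x)
}

#' Generate coordinates for a batch of SMILES
#'
#' Each failure yields a per-molecule error record, never a batch abort.
#' Successful records are written to `out_sdf` (input order preserved) when
#' given.
#'
#' @param smiles character vector of SMILES (names become record titles).
#' @param lib,templates,min_atoms,amide_rotatable see
#'   [generate_coordinates()].
#' @param out_sdf optional SD file for the generated structures.
#' @return list with `results` (per-molecule `generate_coordinates()` output
#'   or `NULL`), and `summary` (data frame: smiles, ok, provenance counts,
#'   closures, corrections, error message).
#' @export
generate_batch <- function(smiles, lib = NULL, templates = generic_ring_templates(),
                           min_atoms = 5L, amide_rotatable = FALSE, out_sdf = NULL) {
  results <- vector("list", length(smiles))
  rows <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    res <- tryCatch(
      generate_coordinates(smiles[i], lib, templates, min_atoms, amide_rotatable),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(smiles = smiles[i], ok = FALSE, n_fragment_atoms = NA,
                              n_rule_atoms = NA, n_long_closures = NA,
                              stereo_corrections = NA,
                              error = conditionMessage(res))
    } else {
      results[[i]] <- res
      r <- res$report
      rows[[i]] <- data.frame(smiles = smiles[i], ok = TRUE,
                              n_fragment_atoms = r$n_fragment_atoms,
                              n_rule_atoms = r$n_rule_atoms,
                              n_long_closures = nrow(r$long_closure_bonds),
                              stereo_corrections = r$stereo_corrections,
                              error = "")
    }
  }
  if (!is.null(out_sdf)) {
    ok <- !vapply(results, is.null, logical(1))
    mols <- lapply(results[ok], `[[`, "mol")
    nm <- if (!is.null(names(smiles))) names(smiles)[ok] else smiles[ok]
    write_sdf(mols, out_sdf, names = nm)
  }
  list(results = results, summary = do.call(rbind, rows))
}
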