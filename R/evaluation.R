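# Conformer evaluation: symmetry-aware heavy-atom RMSD (optimal rigid
# superposition minimized over graph automorphisms), internal-coordinate
# errors (bond / angle / torsion), torsion fingerprint deviation, InChIKey
# stereo success, and batch aggregation.

# colored igraph over the heavy-atom skeleton; colors encode element+charge
# (vertices) and normalized bond order with aromatic as its own class (edges)
#' @noRd
.colored_graph <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  ridx <- match(seq_len(n_atoms(mol)), heavy)
  keep <- mol$bonds$a %in% heavy & mol$bonds$b %in% heavy
  b <- mol$bonds[keep, , drop = FALSE]
  vcol <- as.integer(factor(paste(mol$atoms$element[heavy], mol$atoms$charge[heavy]),
                            levels = sort(unique(paste(mol$atoms$element[heavy],
                                                       mol$atoms$charge[heavy])))))
  ecol <- ifelse(b$aromatic, 4L, b$order)
  g <- igraph::graph_from_data_frame(
    d = data.frame(a = ridx[b$a], b = ridx[b$b]),
    directed = FALSE,
    vertices = data.frame(name = seq_along(heavy)))
  list(g = g, vcol = vcol, ecol = as.integer(ecol), heavy = heavy,
       key = paste(mol$atoms$element[heavy], mol$atoms$charge[heavy]))
}

# All graph isomorphisms ref -> gen over heavy atoms, as a list of integer
# vectors sigma with sigma[i] = gen heavy position of ref heavy position i.
# NULL when the graphs differ.
#' @noRd
.heavy_isomorphisms <- function(ref, gen, cap = 10000L) {
  gr <- .colored_graph(ref); gg <- .colored_graph(gen)
  if (length(gr$heavy) != length(gg$heavy)) return(NULL)
  # vertex colors must come from a shared level set
  lev <- sort(unique(c(gr$key, gg$key)))
  vc1 <- match(gr$key, lev); vc2 <- match(gg$key, lev)
  n_iso <- igraph::graph.count.isomorphisms.vf2(
    gr$g, gg$g, vertex.color1 = vc1, vertex.color2 = vc2,
    edge.color1 = gr$ecol, edge.color2 = gg$ecol)
  if (n_iso == 0) return(NULL)
  if (n_iso > cap) {
    warning("more than ", cap, " automorphisms; falling back to the identity mapping",
            call. = FALSE)
    if (!identical(vc1, vc2)) return(NULL)
    return(list(seq_along(gr$heavy)))
  }
  maps <- igraph::graph.get.isomorphisms.vf2(
    gr$g, gg$g, vertex.color1 = vc1, vertex.color2 = vc2,
    edge.color1 = gr$ecol, edge.color2 = gg$ecol)
  lapply(maps, as.integer)
}

# First colored isomorphism g1 -> g2 including hydrogen counts in the vertex
# colors (used to map a re-parsed fragment key onto the fragment subgraph);
# NULL when none exists. Deterministic: VF2 with a fixed search order.
#' @noRd
.first_isomorphism <- function(m1, m2) {
  g1 <- .colored_graph(m1); g2 <- .colored_graph(m2)
  if (length(g1$heavy) != length(g2$heavy)) return(NULL)
  k1 <- paste(g1$key, m1$atoms$nH[g1$heavy])
  k2 <- paste(g2$key, m2$atoms$nH[g2$heavy])
  lev <- sort(unique(c(k1, k2)))
  maps <- igraph::graph.get.isomorphisms.vf2(
    g1$g, g2$g, vertex.color1 = match(k1, lev), vertex.color2 = match(k2, lev),
    edge.color1 = g1$ecol, edge.color2 = g2$ecol)
  if (!length(maps)) return(NULL)
  as.integer(maps[[1]])
}

#' @noRd
.heavy_coords <- function(mol) {
  if (is.null(mol$coords)) stop("molecule has no coordinates", call. = FALSE)
  mol$coords[mol$atoms$element != "H", , drop = FALSE]
}

#' Symmetry-aware heavy-atom RMSD
#'
#' Minimum root-mean-square deviation over rigid superposition (optimal
#' rotation + translation) and over graph automorphisms of the heavy-atom
#' skeleton, so symmetric rings are never over-penalized. Automorphism
#' enumeration is capped (identity fallback with a warning beyond the cap);
#' `symmetry_aware = FALSE` gives the plain Kabsch value for comparison.
#'
#' @param ref,gen two `molgraph` objects with coordinates and identical
#'   molecular graphs.
#' @param symmetry_aware minimize over automorphisms (default) or use the
#'   identity mapping only.
#' @param cap automorphism cap.
#' @return RMSD in Angstrom.
#' @export
heavy_atom_rmsd <- function(ref, gen, symmetry_aware = TRUE, cap = 10000L) {
  maps <- .heavy_isomorphisms(ref, gen, cap)
  if (is.null(maps)) stop("molecular graphs differ; RMSD undefined", call. = FALSE)
  if (!symmetry_aware) maps <- maps[1]
  x <- .heavy_coords(ref); y <- .heavy_coords(gen)
  if (!symmetry_aware) {
    # identity mapping: ref atom i against gen atom i
    return(kabsch(x, y)$rmsd)
  }
  min(vapply(maps, function(s) kabsch(x, y[s, , drop = FALSE])$rmsd, numeric(1)))
}

# best-RMSD correspondence (used by the internal-coordinate metrics)
#' @noRd
.best_mapping <- function(ref, gen, cap = 10000L) {
  maps <- .heavy_isomorphisms(ref, gen, cap)
  if (is.null(maps)) stop("molecular graphs differ", call. = FALSE)
  x <- .heavy_coords(ref); y <- .heavy_coords(gen)
  r <- vapply(maps, function(s) kabsch(x, y[s, , drop = FALSE])$rmsd, numeric(1))
  maps[[which.min(r)]]
}

# bonded triples (angles) and quadruples (torsions) of the heavy skeleton
#' @noRd
.heavy_graph_paths <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  ridx <- match(seq_len(n_atoms(mol)), heavy)
  keep <- mol$bonds$a %in% heavy & mol$bonds$b %in% heavy
  b <- mol$bonds[keep, , drop = FALSE]
  n <- length(heavy)
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    i <- ridx[b$a[k]]; j <- ridx[b$b[k]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, sort)
  bonds <- cbind(ridx[b$a], ridx[b$b])
  angles <- NULL
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2L) {
      cmb <- utils::combn(nb, 2)
      angles <- rbind(angles, cbind(cmb[1, ], j, cmb[2, ]))
    }
  }
  torsions <- NULL
  for (k in seq_len(nrow(bonds))) {
    bb <- bonds[k, 1]; cc <- bonds[k, 2]
    for (aa in setdiff(adj[[bb]], cc)) {
      for (dd in setdiff(adj[[cc]], bb)) {
        if (aa != dd) torsions <- rbind(torsions, c(aa, bb, cc, dd))
      }
    }
  }
  list(adj = adj, bonds = bonds, angles = angles, torsions = torsions,
       in_ring = b$in_ring, order = b$order, aromatic = b$aromatic)
}

#' Internal coordinate errors between two conformers
#'
#' Mean absolute differences over all heavy-atom bonds (Angstrom), bonded
#' angle triples (degrees), and bonded torsion quadruples (degrees, absolute
#' circular difference mapped to [0, 180]). Atom correspondence is the
#' best-RMSD graph isomorphism, so symmetric molecules are handled
#' consistently with [heavy_atom_rmsd()].
#'
#' @param ref,gen two `molgraph` objects with coordinates, same graph.
#' @return list with `mean_bond`, `mean_angle`, `mean_torsion`.
#' @export
internal_coordinate_errors <- function(ref, gen) {
  s <- .best_mapping(ref, gen)
  x <- .heavy_coords(ref); y <- .heavy_coords(gen)
  p <- .heavy_graph_paths(ref)
  dbond <- vapply(seq_len(nrow(p$bonds)), function(k) {
    a <- p$bonds[k, 1]; b <- p$bonds[k, 2]
    abs(vnorm(x[a, ] - x[b, ]) - vnorm(y[s[a], ] - y[s[b], ]))
  }, numeric(1))
  dang <- if (is.null(p$angles)) numeric(0) else vapply(seq_len(nrow(p$angles)), function(k) {
    a <- p$angles[k, 1]; j <- p$angles[k, 2]; b <- p$angles[k, 3]
    abs(angle_between(x[a, ] - x[j, ], x[b, ] - x[j, ]) -
          angle_between(y[s[a], ] - y[s[j], ], y[s[b], ] - y[s[j], ]))
  }, numeric(1))
  dtor <- if (is.null(p$torsions)) numeric(0) else vapply(seq_len(nrow(p$torsions)), function(k) {
    q <- p$torsions[k, ]
    t1 <- tryCatch(dihedral(x[q[1], ], x[q[2], ], x[q[3], ], x[q[4], ]), error = function(e) NA_real_)
    t2 <- tryCatch(dihedral(y[s[q[1]], ], y[s[q[2]], ], y[s[q[3]], ], y[s[q[4]], ]), error = function(e) NA_real_)
    if (is.na(t1) || is.na(t2)) NA_real_ else circular_diff(t1, t2)
  }, numeric(1))
  dtor <- dtor[!is.na(dtor)]
  list(mean_bond = if (length(dbond)) mean(dbond) else 0,
       mean_angle = if (length(dang)) mean(dang) else 0,
       mean_torsion = if (length(dtor)) mean(dtor) else 0)
}

#' Torsion fingerprint deviation
#'
#' Normalized, hydrogen-free torsional difference in [0, 1]: per torsion bond
#' (acyclic bonds between non-terminal heavy atoms, plus ring bonds) the
#' minimal absolute circular deviation over all reference substituent pairs
#' (damping substituent-symmetry effects), divided by 180 and averaged with
#' weights 1 / (1 + d), where d is the bond's topological distance from the
#' graph center of the molecule. Identical conformers give 0; a single
#' torsion flipped from anti to eclipsed gives 1.
#'
#' @param ref,gen two `molgraph` objects with coordinates, same graph.
#' @return TFD value in [0, 1] (0, with a message, for molecules without
#'   torsions).
#' @export
torsion_fingerprint_deviation <- function(ref, gen) {
  s <- .best_mapping(ref, gen)
  x <- .heavy_coords(ref); y <- .heavy_coords(gen)
  p <- .heavy_graph_paths(ref)
  deg <- lengths(p$adj)
  tb <- which((!p$in_ring & deg[p$bonds[, 1]] >= 2L & deg[p$bonds[, 2]] >= 2L) | p$in_ring)
  tb <- tb[deg[p$bonds[tb, 1]] >= 2L & deg[p$bonds[tb, 2]] >= 2L]
  if (!length(tb)) {
    message("molecule has no torsions; TFD defined as 0")
    return(0)
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(a = p$bonds[, 1], b = p$bonds[, 2]), directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(x))))
  ecc <- igraph::eccentricity(g)
  centers <- which(ecc == min(ecc))
  dist_to_center <- igraph::distances(g, v = igraph::V(g), to = centers)
  dmin <- apply(dist_to_center, 1, min)

  devs <- c(); wts <- c()
  for (k in tb) {
    bb <- p$bonds[k, 1]; cc <- p$bonds[k, 2]
    ra <- setdiff(p$adj[[bb]], cc); rd <- setdiff(p$adj[[cc]], bb)
    if (!length(ra) || !length(rd)) next
    best <- Inf
    for (aa in ra) for (dd in rd) {
      if (aa == dd) next
      t1 <- tryCatch(dihedral(x[aa, ], x[bb, ], x[cc, ], x[dd, ]), error = function(e) NA_real_)
      t2 <- tryCatch(dihedral(y[s[aa], ], y[s[bb], ], y[s[cc], ], y[s[dd], ]), error = function(e) NA_real_)
      if (is.na(t1) || is.na(t2)) next
      best <- min(best, circular_diff(t1, t2))
    }
    if (!is.finite(best)) next
    devs <- c(devs, best / 180)
    wts <- c(wts, 1 / (1 + min(dmin[bb], dmin[cc])))
  }
  if (!length(devs)) {
    message("molecule has no measurable torsions; TFD defined as 0")
    return(0)
  }
  sum(wts * devs) / sum(wts)
}

#' Stereochemistry success check
#'
#' `TRUE` iff the InChIKey of the input SMILES equals the InChIKey of the
#' generated molecule with stereo perceived from its 3D coordinates. InChI
#' failures count as `FALSE` (and are logged by the key generator).
#'
#' @param input_smiles the SMILES the structure was generated from.
#' @param gen generated `molgraph` with coordinates.
#' @return logical.
#' @export
stereo_success <- function(input_smiles, gen) {
  isTRUE(inchikey(input_smiles) == inchikey(gen))
}

#' Evaluate a batch of generated structures against references
#'
#' Records are matched by SD title where available (falling back to file
#' order). Aggregate means are computed over stereo-successful molecules
#' only; a flag includes failures for sensitivity analysis.
#'
#' @param ref references: SD file path or list of `molgraph`.
#' @param gen generated structures: SD file path or list of `molgraph`.
#' @param smiles optional character vector (or .smi file path) of input
#'   SMILES for the stereo check; defaults to the reference InChIKeys.
#' @param include_failures include stereo-failed molecules in the means.
#' @param out_tsv optional path for a per-molecule TSV (columns in the metric
#'   order RMSD, Bond, Angle, Torsion, TFD, Success).
#' @return a `batch_report`: `per_molecule` data frame, `means`,
#'   `success_rate` (percent), `n_failed`, `n`.
#' @export
evaluate_batch <- function(ref, gen, smiles = NULL, include_failures = FALSE,
                           out_tsv = NULL) {
  if (is.character(ref)) ref <- read_sdf(ref)
  if (is.character(gen)) gen <- read_sdf(gen)
  if (!is.null(smiles) && length(smiles) == 1L && file.exists(smiles)) {
    smiles <- vapply(strsplit(trimws(readLines(smiles, warn = FALSE)), "[ \t]+"),
                     `[[`, "", 1)
  }
  ref_names <- vapply(ref, function(m) m$source_id %||% "", "")
  gen_names <- vapply(gen, function(m) m$source_id %||% "", "")
  if (all(nzchar(ref_names)) && all(nzchar(gen_names)) &&
      !anyDuplicated(ref_names) && !anyDuplicated(gen_names)) {
    common <- intersect(ref_names, gen_names)
    unmatched <- length(ref) + length(gen) - 2L * length(common)
    ref <- ref[match(common, ref_names)]
    gen <- gen[match(common, gen_names)]
    if (!is.null(smiles)) smiles <- smiles[match(common, ref_names)]
    ids <- common
  } else {
    n <- min(length(ref), length(gen))
    unmatched <- length(ref) + length(gen) - 2L * n
    ref <- ref[seq_len(n)]; gen <- gen[seq_len(n)]
    ids <- ifelse(nzchar(ref_names[seq_len(n)]), ref_names[seq_len(n)],
                  as.character(seq_len(n)))
  }
  if (unmatched > 0) warning(unmatched, " unmatched record(s) skipped", call. = FALSE)

  keys_ref <- if (is.null(smiles)) inchikey(ref) else inchikey(smiles)
  keys_gen <- inchikey(gen)

  rows <- lapply(seq_along(ref), function(i) {
    ok <- isTRUE(keys_ref[i] == keys_gen[i])
    m <- tryCatch({
      ic <- internal_coordinate_errors(ref[[i]], gen[[i]])
      data.frame(id = ids[i],
                 rmsd = heavy_atom_rmsd(ref[[i]], gen[[i]]),
                 mean_bond = ic$mean_bond, mean_angle = ic$mean_angle,
                 mean_torsion = ic$mean_torsion,
                 tfd = suppressMessages(torsion_fingerprint_deviation(ref[[i]], gen[[i]])),
                 stereo_ok = ok, failed = FALSE)
    }, error = function(e) {
      data.frame(id = ids[i], rmsd = NA_real_, mean_bond = NA_real_,
                 mean_angle = NA_real_, mean_torsion = NA_real_, tfd = NA_real_,
                 stereo_ok = FALSE, failed = TRUE)
    })
    m
  })
  per <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(id = character(0), rmsd = numeric(0), mean_bond = numeric(0),
               mean_angle = numeric(0), mean_torsion = numeric(0),
               tfd = numeric(0), stereo_ok = logical(0), failed = logical(0))
  }
  sel <- if (include_failures) !per$failed else per$stereo_ok & !per$failed
  means <- if (any(sel)) {
    colMeans(per[sel, c("rmsd", "mean_bond", "mean_angle", "mean_torsion", "tfd")])
  } else {
    stats::setNames(rep(NA_real_, 5), c("rmsd", "mean_bond", "mean_angle", "mean_torsion", "tfd"))
  }
  rep_obj <- structure(list(
    per_molecule = per,
    means = as.list(means),
    success_rate = if (nrow(per)) 100 * mean(per$stereo_ok) else NA_real_,
    n_failed = sum(per$failed),
    n = nrow(per)
  ), class = "batch_report")
  if (!is.null(out_tsv)) {
    utils::write.table(per, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep_obj
}

#' @export
print.batch_report <- function(x, ...) {
  cat(sprintf("<batch_report> n=%d  success=%.1f%%  failed=%d\n", x$n,
              x$success_rate, x$n_failed))
  if (x$n && !all(is.na(unlist(x$means)))) {
    cat(sprintf("  means over successful molecules: RMSD %.3f A | bond %.4f A | angle %.2f deg | torsion %.1f deg | TFD %.3f\n",
                x$means$rmsd, x$means$mean_bond, x$means$mean_angle,
                x$means$mean_torsion, x$means$tfd))
  }
  invisible(x)
}
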