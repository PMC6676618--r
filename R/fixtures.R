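# Deterministic toy fixtures: idealized geometries constructed analytically
# (regular polygons, chairs, crowns, tetrahedra), a corpus emitter with
# optional seeded jitter, and a stereochemistry test suite. These stand in
# for mined 3D corpora so that every module is testable with no download.

.fixture_builders <- function() list(
  benzene = function() {
    molgraph(
      data.frame(element = rep("C", 6), nH = 1L, aromatic = TRUE),
      data.frame(a = 1:6, b = c(2:6, 1L), order = rep(c(2L, 1L), 3), aromatic = TRUE),
      coords = .polygon_coords(6, 1.39), source_id = "benzene")
  },
  cyclohexane_chair = function() {
    molgraph(
      data.frame(element = rep("C", 6), nH = 2L),
      data.frame(a = 1:6, b = c(2:6, 1L), order = 1L),
      coords = .chair_coords(1.54), source_id = "cyclohexane_chair")
  },
  cyclopentane = function() {
    molgraph(
      data.frame(element = rep("C", 5), nH = 2L),
      data.frame(a = 1:5, b = c(2:5, 1L), order = 1L),
      coords = .envelope_coords(1.54), source_id = "cyclopentane")
  },
  pyridine = function() {
    molgraph(
      data.frame(element = c("N", rep("C", 5)), nH = c(0L, rep(1L, 5)), aromatic = TRUE),
      data.frame(a = 1:6, b = c(2:6, 1L), order = rep(c(2L, 1L), 3), aromatic = TRUE),
      coords = .polygon_coords(6, 1.39), source_id = "pyridine")
  },
  naphthalene = function() {
    s <- 1.39; ap <- s * sqrt(3) / 2
    th <- function(deg) .rad(deg)
    c1 <- c(ap, 0)
    ring_a <- t(vapply(c(90, 30, -30, -90), function(d) c1 + s * c(cos(th(d)), sin(th(d))), numeric(2)))
    ring_b <- ring_a[4:1, , drop = FALSE] %*% diag(c(-1, 1))
    xy <- rbind(ring_a,                      # C1 C2 C3 C4
                c(0, -s / 2),                # C4a
                ring_b,                      # C5 C6 C7 C8
                c(0, s / 2))                 # C8a
    molgraph(
      data.frame(element = rep("C", 10),
                 nH = c(1L, 1L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L),
                 aromatic = TRUE),
      data.frame(a = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 5),
                 b = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 1, 10),
                 order = c(2L, 1L, 2L, 1L, 1L, 2L, 1L, 2L, 1L, 1L, 2L),
                 aromatic = TRUE),
      coords = cbind(xy, 0), source_id = "naphthalene")
  },
  biphenyl = function() {
    s <- 1.39
    ring1 <- .polygon_coords(6, s)                       # atom 1 at (+r, 0)
    shift <- 2 * s / (2 * sin(pi / 6)) + 1.52            # 2r + inter-ring bond
    ring2 <- ring1; ring2[, 1] <- shift - ring2[, 1]     # mirrored copy; atom 7 faces atom 1
    molgraph(
      data.frame(element = rep("C", 12),
                 nH = c(0L, rep(1L, 5), 0L, rep(1L, 5)), aromatic = TRUE),
      data.frame(a = c(1:6, 7:12, 1),
                 b = c(2:6, 1, 8:12, 7, 7),
                 order = c(rep(c(2L, 1L), 3), rep(c(2L, 1L), 3), 1L),
                 aromatic = c(rep(TRUE, 12), FALSE)),
      coords = rbind(ring1, ring2), source_id = "biphenyl")
  },
  butane_anti = function() {
    d <- 1.52; a2 <- .rad(109.47) / 2
    step <- function(k) d * c(sin(a2), cos(a2) * (-1)^k, 0)
    pos <- rbind(c(0, 0, 0))
    for (k in 1:3) pos <- rbind(pos, pos[k, ] + step(k))
    molgraph(
      data.frame(element = rep("C", 4), nH = c(3L, 2L, 2L, 3L)),
      data.frame(a = 1:3, b = 2:4, order = 1L),
      coords = pos, source_id = "butane_anti")
  },
  tetrahedral_center = function() {
    t1 <- c(0, 0, 1); t2 <- c(2 * sqrt(2) / 3, 0, -1 / 3)
    t3 <- c(-sqrt(2) / 3, sqrt(6) / 3, -1 / 3)
    molgraph(
      data.frame(element = c("C", "F", "Cl", "Br"), nH = c(1L, 0L, 0L, 0L)),
      data.frame(a = c(1, 1, 1), b = 2:4, order = 1L),
      coords = rbind(c(0, 0, 0),
                     t1 * ideal_bond_length("C", "F"),
                     t2 * ideal_bond_length("C", "Cl"),
                     t3 * ideal_bond_length("C", "Br")),
      source_id = "tetrahedral_center")
  },
  trans_2_butene = function() {
    molgraph(
      data.frame(element = rep("C", 4), nH = c(3L, 1L, 1L, 3L)),
      data.frame(a = 1:3, b = 2:4, order = c(1L, 2L, 1L)),
      coords = rbind(c(-0.76, 1.52 * sin(.rad(60)), 0),
                     c(0, 0, 0),
                     c(1.32, 0, 0),
                     c(1.32 + 0.76, -1.52 * sin(.rad(60)), 0)),
      source_id = "trans_2_butene")
  },
  macrocycle_12 = function() {
    molgraph(
      data.frame(element = rep("C", 12), nH = 2L),
      data.frame(a = 1:12, b = c(2:12, 1L), order = 1L),
      coords = .crown_coords(12, 1.54), source_id = "macrocycle_12")
  }
)

#' Names of the built-in fixtures
#' @return character vector of fixture names.
#' @export
fixture_names <- function() names(.fixture_builders())

#' Idealized fixture geometry
#'
#' Hard-coded, analytically constructed reference geometries (e.g. benzene as
#' a regular hexagon with 1.39 A sides; cyclohexane as a standard chair with
#' 1.54 A bonds). These are engine-independent ground truth for tests and toy
#' corpora.
#'
#' @param name one of [fixture_names()].
#' @return a `molgraph` with coordinates.
#' @export
idealized_geometry <- function(name) {
  builders <- .fixture_builders()
  if (!name %in% names(builders)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(builders), collapse = ", "), call. = FALSE)
  }
  builders[[name]]()
}

#' Emit a fixture corpus
#'
#' Each requested fixture is emitted `n_copies` times; copies after the first
#' can carry seeded Gaussian coordinate jitter, so occurrence-count thresholds
#' and the first-conformer storage policy are directly exercisable. With the
#' same seed the output is bit-identical.
#'
#' @param set fixture names (default: all).
#' @param n_copies copies per fixture (>= 1).
#' @param jitter_sigma standard deviation (Angstrom) of coordinate jitter
#'   applied to copies after the first.
#' @param seed RNG seed for the jitter.
#' @param path optional SD file to write.
#' @return invisibly, the list of `molgraph` records (also written to `path`
#'   if given).
#' @export
build_fixture_corpus <- function(set = fixture_names(), n_copies = 3L,
                                 jitter_sigma = 0, seed = 1L, path = NULL) {
  stopifnot(n_copies >= 1L)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  mols <- list()
  for (nm in set) {
    base <- idealized_geometry(nm)
    for (k in seq_len(n_copies)) {
      m <- base
      m$source_id <- sprintf("%s_%d", nm, k)
      if (k > 1L && jitter_sigma > 0) {
        m$coords <- m$coords + matrix(stats::rnorm(length(m$coords), sd = jitter_sigma),
                                      nrow = nrow(m$coords))
      }
      mols[[length(mols) + 1L]] <- m
    }
  }
  if (!is.null(path)) write_sdf(mols, path)
  invisible(mols)
}

#' Stereochemistry test suite
#'
#' A fixed panel of fully stereo-annotated SMILES: single and multiple R/S
#' centers, cis/trans double bonds, conjugated diene configurations, ring and
#' ring-fused stereocenters, and a stereocenter on a macrocycle. Expected
#' InChIKeys are computed at call time (never hard-coded), so the suite always
#' reflects the engine in use.
#'
#' @return data frame with columns `smiles` and `inchikey`.
#' @export
stereo_suite <- function() {
  smiles <- c(
    "F[C@H](Cl)Br", "F[C@@H](Cl)Br",
    "C[C@H](O)CC", "C[C@@H](O)CC",
    "N[C@@H](C)C(=O)O", "N[C@H](C)C(=O)O",
    "C/C=C/C", "C/C=C\\C",
    "C/C=C/C=C/C", "C/C=C\\C=C/C",
    "F/C=C/F", "F/C=C\\F",
    "OC/C=C/CO", "OC/C=C\\CO",
    "CC(=O)O[C@H](C)CC",
    "N[C@@H](CC1=CC=CC=C1)C(=O)O",
    "N[C@@H](CO)C(=O)O", "N[C@@H](CS)C(=O)O",
    "C[C@@H](O)[C@H](N)C(=O)O", "C[C@H](O)[C@H](N)C(=O)O",
    "OC(=O)[C@H](O)[C@@H](O)C(=O)O", "OC(=O)[C@H](O)[C@H](O)C(=O)O",
    "OC[C@@H](O)C=O", "OC[C@H](O)C=O",
    "C[C@H]1CO1", "C[C@@H]1CO1",
    "C[C@H]1CCC[C@@H]1C", "C[C@H]1CCC[C@H]1C",
    "C1CC[C@@H]2CCCC[C@H]2C1", "C1CC[C@H]2CCCC[C@H]2C1",
    "CC(C)[C@@H]1CC[C@@H](C)C[C@H]1O",
    "C[C@H](N)C(=O)NC",
    "CC(=O)N[C@@H](C)C(=O)O",
    "C[C@H]1CCCCCOCCCC1",
    "F[C@](Cl)(Br)CC", "F[C@@](Cl)(Br)CC",
    "N[C@@H](CCC(=O)O)C(=O)O",
    "C[C@@H](Cl)/C=C/C"
  )
  data.frame(smiles = smiles, inchikey = inchikey(smiles), stringsAsFactors = FALSE)
}
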