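# Metric suite: symmetry-aware RMSD, internal coordinate errors, TFD, stereo
# success, batch aggregation.

test_that("RMSD obeys its closed forms and invariances", {
  bz <- idealized_geometry("benzene")
  expect_lt(heavy_atom_rmsd(bz, bz), 1e-12)

  # rigid motion invariance, property-style over seeded random transforms
  set.seed(101)
  for (rep in 1:20) {
    R <- random_rotation()
    t <- stats::rnorm(3, sd = 5)
    moved <- bz
    moved$coords <- sweep(bz$coords %*% t(R), 2, t, `+`)
    expect_lt(heavy_atom_rmsd(bz, moved), 1e-6)
  }

  # two collinear points, separations 2 vs 4: closed-form RMSD 1.0
  two <- function(d) molgraph(data.frame(element = c("C", "C"), nH = 3L),
                              data.frame(a = 1L, b = 2L, order = 1L),
                              coords = rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(heavy_atom_rmsd(two(2), two(4)), 1.0, tolerance = 1e-9)

  # symmetry
  ch <- idealized_geometry("cyclohexane_chair")
  gen <- generate_coordinates("C1CCCCC1", fixture_library())$mol
  expect_equal(heavy_atom_rmsd(ch, gen), heavy_atom_rmsd(gen, ch), tolerance = 1e-9)

  # graph mismatch is an error
  expect_error(heavy_atom_rmsd(bz, idealized_geometry("pyridine")), "differ")
})

test_that("symmetry-aware RMSD never exceeds the identity-mapping RMSD", {
  set.seed(202)
  for (nm in c("benzene", "cyclohexane_chair", "naphthalene", "biphenyl")) {
    fix <- idealized_geometry(nm)
    for (rep in 1:5) {
      moved <- fix
      moved$coords <- sweep(fix$coords %*% t(random_rotation()), 2,
                            stats::rnorm(3, sd = 2), `+`)
      # also scramble by a graph automorphism so identity is suboptimal
      sym <- heavy_atom_rmsd(fix, moved)
      ident <- heavy_atom_rmsd(fix, moved, symmetry_aware = FALSE)
      expect_lte(sym, ident + 1e-12)
      expect_lt(sym, 1e-6)
    }
  }
  perm <- idealized_geometry("benzene")
  perm$coords <- perm$coords[c(2:6, 1), ]
  base <- idealized_geometry("benzene")
  expect_lt(heavy_atom_rmsd(base, perm), 1e-9)
})

test_that("internal coordinate errors match hand computations", {
  bt <- idealized_geometry("butane_anti")
  same <- internal_coordinate_errors(bt, bt)
  expect_equal(same$mean_bond, 0)
  expect_equal(same$mean_angle, 0)
  expect_equal(same$mean_torsion, 0)

  # stretch one terminal bond by +0.1 along its axis: 3 bonds -> mean 0.1/3
  st <- bt
  u <- fragcoord:::unit(bt$coords[4, ] - bt$coords[3, ])
  st$coords[4, ] <- st$coords[4, ] + 0.1 * u
  ic <- internal_coordinate_errors(bt, st)
  expect_equal(ic$mean_bond, 0.1 / 3, tolerance = 1e-9)
  expect_equal(ic$mean_angle, 0, tolerance = 1e-6)

  # circular difference: 170 vs -170 contributes 20, not 340
  expect_equal(fragcoord:::circular_diff(170, -170), 20)
  expect_equal(fragcoord:::circular_diff(-179, 179), 2)
})

test_that("TFD satisfies its normalization contracts", {
  bt <- idealized_geometry("butane_anti")
  expect_equal(torsion_fingerprint_deviation(bt, bt), 0)

  # anti vs eclipsed on the single torsion: maximal deviation, TFD = 1
  ec <- bt
  ax <- bt$coords[3, ] - bt$coords[2, ]
  R <- fragcoord:::rotation_about(ax, pi)
  ec$coords[4, ] <- bt$coords[3, ] + as.numeric(R %*% (bt$coords[4, ] - bt$coords[3, ]))
  expect_equal(torsion_fingerprint_deviation(bt, ec), 1.0, tolerance = 1e-9)

  # bounded in [0, 1], rigid-motion invariant
  set.seed(99)
  mc <- idealized_geometry("macrocycle_12")
  gen <- generate_coordinates("C1CCCCCCCCCCC1", NULL, NULL)$mol
  v <- torsion_fingerprint_deviation(mc, gen)
  expect_gte(v, 0); expect_lte(v, 1)
  moved <- gen
  moved$coords <- sweep(gen$coords %*% t(random_rotation()), 2, c(3, -1, 7), `+`)
  expect_equal(torsion_fingerprint_deviation(mc, moved), v, tolerance = 1e-9)

  # no torsions: defined as 0 with a note
  met <- generate_coordinates("C", NULL, NULL)$mol
  expect_message(z <- torsion_fingerprint_deviation(met, met), "TFD")
  expect_equal(z, 0)
})

test_that("stereo success is an InChIKey round trip", {
  bz <- generate_coordinates("c1ccccc1", fixture_library())$mol
  expect_true(stereo_success("c1ccccc1", bz))
  r <- generate_coordinates("F[C@H](Cl)Br", NULL, NULL)$mol
  expect_true(stereo_success("F[C@H](Cl)Br", r))
  expect_false(stereo_success("F[C@@H](Cl)Br", r))
})

test_that("batch evaluation aggregates over stereo-successful molecules", {
  refs <- lapply(c("benzene", "pyridine", "cyclohexane_chair", "tetrahedral_center"),
                 idealized_geometry)
  gens <- lapply(refs, function(m) {
    g <- generate_coordinates(canonical_smiles(m), fixture_library())$mol
    g$source_id <- m$source_id
    g
  })
  # sabotage one record's stereo: mirror the tetrahedral center
  gens[[4]]$coords[, 1] <- -gens[[4]]$coords[, 1]
  rep <- evaluate_batch(refs, gens)
  expect_equal(rep$n, 4L)
  expect_equal(rep$success_rate, 75)
  expect_identical(rep$per_molecule$stereo_ok,
                   c(TRUE, TRUE, TRUE, FALSE))
  # means computed over the 3 successes only: all regenerated exactly
  expect_lt(rep$means$rmsd, 1e-9)
  expect_lt(rep$means$mean_bond, 1e-9)

  # identical files: all-zero metrics, success 100
  self <- evaluate_batch(refs, refs)
  expect_equal(self$success_rate, 100)
  expect_lt(max(self$per_molecule$rmsd), 1e-12)

  # empty batch is flagged, not fatal
  empty <- suppressWarnings(evaluate_batch(list(), list()))
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$success_rate) || is.nan(empty$success_rate))

  # TSV output mirrors the per-molecule table
  tsv <- tempfile()
  evaluate_batch(refs, gens, out_tsv = tsv)
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), 4L)
  expect_true(all(c("rmsd", "mean_bond", "mean_angle", "mean_torsion", "tfd",
                    "stereo_ok") %in% names(tab)))
})

test_that("record pairing falls back from titles to order", {
  refs <- lapply(c("benzene", "pyridine"), idealized_geometry)
  gens <- lapply(refs, function(m) {
    g <- generate_coordinates(canonical_smiles(m), fixture_library())$mol
    g$source_id <- m$source_id
    g
  })
  shuffled <- evaluate_batch(refs, rev(gens))   # titles re-align the records
  expect_equal(shuffled$success_rate, 100)
  expect_lt(max(shuffled$per_molecule$rmsd), 1e-9)
})
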