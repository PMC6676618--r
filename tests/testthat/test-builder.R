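# Coordinate builder: valence geometry, rigid fragment placement, ring
# closures, hydrogens, stereo enforcement, determinism.

test_that("ideal bond lengths come from the radius table and scale factors", {
  expect_equal(ideal_bond_length("C", "C", 1), 1.52)
  expect_equal(ideal_bond_length("C", "O", 1), 1.42)
  expect_equal(ideal_bond_length("C", "H", 1), 1.07)
  expect_equal(ideal_bond_length("C", "C", "ar"), 1.52 * 0.915)
  expect_equal(ideal_bond_length("C", "C", 2), 1.52 * 0.87)
  expect_equal(ideal_bond_length("C", "C", 3), 1.52 * 0.78)
  expect_identical(ideal_bond_length("C", "N", 1), ideal_bond_length("N", "C", 1))
  expect_error(ideal_bond_length("C", "Xx", 1), "Xx")
})

test_that("open valence directions complete the ideal geometries", {
  # a lone sp3 atom exposes the full tetrahedral set
  w <- fragcoord:::new_working_molecule(parse_smiles("C"))
  w <- place_atom_rule_based(w, 1L)
  dirs <- open_valence_directions(w, 1L)
  expect_equal(nrow(dirs), 4L)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(vec_angle(dirs[i, ], dirs[j, ]), 109.4712, tolerance = 1e-2)
  }
  expect_equal(dirs[1, ], c(0, 0, 1), tolerance = 1e-9)

  # sp: one neighbor placed -> single antipodal direction
  co2 <- parse_smiles("O=C=O")
  w2 <- fragcoord:::new_working_molecule(co2)
  w2 <- place_atom_rule_based(w2, 2L)          # central sp carbon at origin
  w2 <- place_atom_rule_based(w2, 1L, 2L)
  d <- open_valence_directions(w2, 2L)
  expect_equal(nrow(d), 1L)
  u <- (w2$coords[1, ] - w2$coords[2, ]); u <- u / sqrt(sum(u^2))
  expect_equal(as.numeric(d[1, ] + u), c(0, 0, 0), tolerance = 1e-9)

  # sp2 with two placed neighbors at 120 degrees: remaining direction is
  # coplanar and 120 degrees from both
  bz <- parse_smiles("c1ccccc1")
  w3 <- fragcoord:::new_working_molecule(bz)
  w3 <- place_atom_rule_based(w3, 2L)
  w3 <- place_atom_rule_based(w3, 1L, 2L)
  w3 <- place_atom_rule_based(w3, 3L, 2L)
  d3 <- open_valence_directions(w3, 2L)
  expect_equal(nrow(d3), 1L)
  u1 <- w3$coords[1, ] - w3$coords[2, ]; u3 <- w3$coords[3, ] - w3$coords[2, ]
  expect_equal(vec_angle(d3[1, ], u1), 120, tolerance = 0.02)
  expect_equal(vec_angle(d3[1, ], u3), 120, tolerance = 0.02)
  expect_lt(abs(det(rbind(d3[1, ], u1, u3))), 1e-4)  # coplanar

  expect_error(open_valence_directions(w3, 5L), "not placed")
})

test_that("rule placement honors lengths, the anti torsion, and the origin convention", {
  res <- generate_coordinates("CCCC", NULL, NULL)
  m <- res$mol
  expect_equal(m$coords[1, ], c(0, 0, 0))
  expect_equal(dihedral4(m$coords[1:4, ]), 180, tolerance = 0.5)
  expect_true(all(res$report$provenance == "rule"))

  res6 <- generate_coordinates("CCCCCC", NULL, NULL)
  for (i in 1:3) {
    expect_equal(abs(dihedral4(res6$mol$coords[i:(i + 3), ])), 180, tolerance = 0.5)
  }

  # every placed bond at its ideal length
  bl <- bond_lengths(res6$mol)
  ideal <- vapply(seq_len(nrow(res6$mol$bonds)), function(k)
    fragcoord:::ideal_length_for_bond(res6$mol, k), numeric(1))
  expect_true(all(abs(bl - ideal) < 1e-3))
})

test_that("hydrogen placement completes the valence geometry", {
  met <- generate_coordinates("C", NULL, NULL)$mol
  expect_equal(n_atoms(met), 5L)
  hd <- sweep(met$coords[2:5, ], 2, met$coords[1, ])
  angs <- c()
  for (i in 1:3) for (j in (i + 1):4) angs <- c(angs, vec_angle(hd[i, ], hd[j, ]))
  expect_true(all(abs(angs - 109.4712) < 0.1))
  expect_true(all(abs(sqrt(rowSums(hd^2)) - 1.07) < 1e-3))

  wat <- generate_coordinates("O", NULL, NULL)$mol
  expect_equal(vec_angle(wat$coords[2, ] - wat$coords[1, ],
                         wat$coords[3, ] - wat$coords[1, ]), 109.4712, tolerance = 0.1)

  # benzene hydrogens lie in the ring plane
  bz <- generate_coordinates("c1ccccc1", fixture_library())$mol
  ring <- bz$coords[1:6, ]
  nrm <- fragcoord:::unit(fragcoord:::cross3(ring[2, ] - ring[1, ], ring[3, ] - ring[1, ]))
  hs <- bz$coords[bz$atoms$element == "H", ]
  offs <- abs((hs - matrix(colMeans(ring), nrow(hs), 3, byrow = TRUE)) %*% nrm)
  expect_true(all(offs < 0.01))
})

test_that("fragment placement is rigid and seats the anchor bond ideally", {
  lib <- fixture_library()
  res <- generate_coordinates("c1ccccc1", lib)
  expect_true(all(res$report$provenance == "fragment_exact"))
  f <- fragment_molecule(parse_smiles("c1ccccc1"))[[1]]
  tmpl <- lookup_exact(lib, f$key)
  expect_lt(fragcoord:::kabsch(res$mol$coords[f$map, ], tmpl$coords)$rmsd, 1e-10)

  bip <- generate_coordinates("c1ccccc1-c1ccccc1", lib)
  expect_equal(bip$report$n_fragment_atoms, 12L)
  expect_equal(bip$report$n_rule_atoms, 0L)
  m <- bip$mol
  inter <- which(!m$bonds$aromatic & m$bonds$a <= 12 & m$bonds$b <= 12 &
                   m$atoms$element[m$bonds$a] == "C" & m$atoms$element[m$bonds$b] == "C")[1]
  L <- sqrt(sum((m$coords[m$bonds$a[inter], ] - m$coords[m$bonds$b[inter], ])^2))
  expect_equal(L, ideal_bond_length("C", "C", 1), tolerance = 1e-3)

  # all intra-fragment pairwise distances conserved to 1e-6 relative
  for (f2 in fragment_molecule(parse_smiles("c1ccccc1-c1ccccc1"))) {
    rec <- lookup_exact(lib, f2$key)
    d_t <- as.matrix(dist(rec$coords))
    d_g <- as.matrix(dist(m$coords[f2$map, ]))
    expect_lt(max(abs(d_g - d_t) / pmax(d_t, 1e-9)), 1e-6)
  }
})

test_that("placing a fragment over already-placed atoms is refused", {
  lib <- fixture_library()
  mol <- parse_smiles("c1ccccc1")
  f <- fragment_molecule(mol)[[1]]
  rec <- lookup_exact(lib, f$key)
  w <- fragcoord:::new_working_molecule(mol)
  w <- place_fragment(w, list(coords = rec$coords), f$map, at = 1L)
  expect_error(place_fragment(w, list(coords = rec$coords), f$map), "overlap")
})

test_that("ring closures are measured, flagged beyond 1.5x ideal, never fixed", {
  lib <- fixture_library()
  expect_equal(nrow(generate_coordinates("c1ccccc1", lib)$report$long_closure_bonds), 0L)
  expect_equal(nrow(generate_coordinates("CCCC", NULL, NULL)$report$long_closure_bonds), 0L)
  # rule-built saturated ring cannot close
  rc <- generate_coordinates("C1CCCCC1", NULL, NULL)
  lc <- rc$report$long_closure_bonds
  expect_gte(nrow(lc), 1L)
  expect_true(all(lc$actual > 1.5 * lc$ideal))
})

test_that("graph, elements, charges and orders are preserved by generation", {
  for (smi in c("CC(=O)[O-]", "c1ccc2ccccc2c1", "C#CC", "CC(=O)NC")) {
    inp <- parse_smiles(smi)
    out <- generate_coordinates(smi, fixture_library())$mol
    heavy <- which(out$atoms$element != "H")
    expect_identical(out$atoms$element[heavy], inp$atoms$element)
    expect_identical(out$atoms$charge[heavy], inp$atoms$charge)
    hb <- out$bonds$a <= length(heavy) & out$bonds$b <= length(heavy)
    expect_identical(out$bonds$order[hb], inp$bonds$order)
    expect_identical(canonical_smiles(parse_smiles(smi)), canonical_smiles(smi))
  }
})

test_that("stereo enforcement corrects inverted centers and configurations", {
  # matching parity: no corrections, untouched coordinates
  r0 <- generate_coordinates("F[C@H](Cl)Br", NULL, NULL)
  r1 <- generate_coordinates("F[C@@H](Cl)Br", NULL, NULL)
  expect_equal(r0$report$stereo_corrections + r1$report$stereo_corrections, 1L)
  expect_true(stereo_success("F[C@H](Cl)Br", r0$mol))
  expect_true(stereo_success("F[C@@H](Cl)Br", r1$mol))

  # trans declared: torsion 180; cis declared: one correction flips it
  rt <- generate_coordinates("C/C=C/C", NULL, NULL)
  expect_equal(abs(dihedral4(rt$mol$coords[1:4, ])), 180, tolerance = 1)
  rc <- generate_coordinates("C/C=C\\C", NULL, NULL)
  expect_equal(rc$report$stereo_corrections, 1L)
  expect_equal(dihedral4(rc$mol$coords[1:4, ]), 0, tolerance = 1)
  expect_true(stereo_success("C/C=C\\C", rc$mol))

  # corrections are logged
  expect_true(any(grepl("double bond", rc$report$log)))
})

test_that("generation is deterministic", {
  lib <- fixture_library()
  smis <- c("CC(C)Cc1ccccc1", "C[C@H]1CCC[C@@H]1C", "CCOC(=O)C")
  s1 <- tempfile(fileext = ".sdf"); s2 <- tempfile(fileext = ".sdf")
  generate_batch(smis, lib, out_sdf = s1)
  generate_batch(smis, lib, out_sdf = s2)
  expect_identical(readBin(s1, "raw", file.size(s1)), readBin(s2, "raw", file.size(s2)))
})

test_that("batch errors are per-molecule records, not aborts", {
  b <- generate_batch(c("CCO", "not-a-smiles(", "c1ccccc1"), NULL, NULL)
  expect_identical(b$summary$ok, c(TRUE, FALSE, TRUE))
  expect_match(b$summary$error[2], "parse failure")
  expect_null(b$results[[2]])
})
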