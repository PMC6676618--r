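# Molecular data model: SMILES parsing, canonicalization, hybridization,
# InChIKey, and the stereo parity convention.

test_that("parsing yields the hand-counted graphs", {
  m <- parse_smiles("C")
  expect_equal(n_atoms(m), 1L)
  expect_equal(nrow(m$bonds), 0L)
  expect_equal(m$atoms$nH, 4L)

  bz <- parse_smiles("c1ccccc1")
  expect_equal(n_atoms(bz), 6L)
  expect_equal(nrow(bz$bonds), 6L)
  expect_true(all(bz$atoms$aromatic))
  expect_true(all(bz$bonds$aromatic))
  expect_true(all(bz$bonds$in_ring))

  cp <- parse_smiles("C1CC1")
  expect_equal(n_atoms(cp), 3L)
  expect_equal(nrow(cp$bonds), 3L)
  expect_true(all(cp$bonds$order == 1L))
  expect_true(all(cp$bonds$in_ring))

  expect_error(parse_smiles("not-a-smiles("), "parse failure")
  expect_error(parse_smiles("CC.CC"), "multi-component")
})

test_that("canonical SMILES is invariant, idempotent, and stereo-aware", {
  expect_identical(canonical_smiles("OCC"), canonical_smiles("CCO"))
  expect_identical(canonical_smiles("c1ccccc1"), canonical_smiles("C1=CC=CC=C1"))
  expect_false(canonical_smiles("F[C@H](Cl)Br") == canonical_smiles("F[C@@H](Cl)Br"))

  for (smi in c("CCO", "c1ccncc1", "F[C@H](Cl)Br", "C/C=C/C", "CC(=O)[O-]")) {
    can <- canonical_smiles(smi)
    expect_identical(canonical_smiles(can), can, label = paste("idempotent:", smi))
  }
})

test_that("parse -> canonical round trip preserves composition", {
  for (smi in c("CCO", "CC(=O)NC", "c1ccc2ccccc2c1", "CC(=O)[O-]")) {
    m1 <- parse_smiles(smi)
    m2 <- parse_smiles(canonical_smiles(smi))
    expect_identical(sort(m1$atoms$element), sort(m2$atoms$element))
    expect_identical(sort(ifelse(m1$bonds$aromatic, 4L, m1$bonds$order)),
                     sort(ifelse(m2$bonds$aromatic, 4L, m2$bonds$order)))
    expect_identical(sum(m1$atoms$charge), sum(m2$atoms$charge))
  }
})

test_that("hybridization follows the graph rules, coordinates never enter", {
  hcn <- parse_smiles("C#N")
  expect_identical(perceive_hybridization(hcn), c("sp", "sp"))
  expect_identical(unique(perceive_hybridization(parse_smiles("c1ccccc1"))), "sp2")
  expect_identical(perceive_hybridization(parse_smiles("C")), "sp3")
  expect_identical(perceive_hybridization(parse_smiles("C=C=C"))[2], "sp")
  ac <- parse_smiles("CC=O")
  expect_identical(perceive_hybridization(ac), c("sp3", "sp2", "sp2"))
  # pyrrole nitrogen is aromatic, hence sp2 despite all-single Kekule bonds
  py <- parse_smiles("c1cc[nH]c1")
  expect_identical(perceive_hybridization(py)[py$atoms$element == "N"], "sp2")
  # same graph, with or without coordinates
  bz <- idealized_geometry("benzene")
  bz0 <- bz; bz0$coords <- NULL
  b <- molgraph(bz$atoms, bz$bonds)
  expect_identical(perceive_hybridization(bz), perceive_hybridization(b))
})

test_that("InChIKeys are standard, spelling-invariant, and stereo-sensitive", {
  k <- inchikey(c("OCC", "CCO"))
  expect_identical(k[1], k[2])
  expect_match(k[1], "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
  ek <- inchikey(c("F[C@H](Cl)Br", "F[C@@H](Cl)Br"))
  expect_false(ek[1] == ek[2])
  expect_identical(substr(ek[1], 1, 14), substr(ek[2], 1, 14))
})

test_that("3D-perceived keys agree with declared-stereo keys", {
  # same molecule with and without coordinates -> same key
  tc <- idealized_geometry("tetrahedral_center")
  expect_identical(inchikey(tc), inchikey(canonical_smiles(tc)))
  tb <- idealized_geometry("trans_2_butene")
  expect_identical(inchikey(tb), inchikey("C/C=C/C"))
})

test_that("the atom parity convention matches the engine on generated 3D structures", {
  skip_if(Sys.which("obabel") == "", "obabel CLI not available")
  for (smi in c("F[C@H](Cl)Br", "F[C@@H](Cl)Br", "N[C@@H](C)C(=O)O")) {
    out <- tempfile(fileext = ".sdf")
    system2("obabel", c(shQuote(paste0("-:", smi)), "-osdf", "--gen3d", "-O", out),
            stdout = FALSE, stderr = FALSE)
    pm <- fragcoord:::parse_molblock(readLines(out))
    centers <- which(pm$atoms$parity != 0L)
    expect_gte(length(centers), 1L)
    xyz <- as.matrix(pm$atoms[, c("x", "y", "z")])
    adj <- lapply(seq_len(nrow(pm$atoms)), function(i) {
      sort(c(pm$bonds$b[pm$bonds$a == i], pm$bonds$a[pm$bonds$b == i]))
    })
    for (i in centers) {
      nbrs <- adj[[i]][1:4]
      expect_equal(fragcoord:::.geometric_parity(xyz, nbrs), pm$atoms$parity[i],
                   label = sprintf("parity convention for %s center %d", smi, i))
    }
    unlink(out)
  }
})

test_that("SDF write/read round trip preserves graph and coordinates", {
  mols <- lapply(c("benzene", "tetrahedral_center", "macrocycle_12"), idealized_geometry)
  path <- tempfile(fileext = ".sdf")
  write_sdf(mols, path)
  back <- read_sdf(path)
  expect_length(back, 3L)
  for (i in seq_along(mols)) {
    expect_identical(back[[i]]$atoms$element, mols[[i]]$atoms$element)
    expect_equal(back[[i]]$coords, mols[[i]]$coords, tolerance = 1e-4)
    expect_identical(back[[i]]$source_id, mols[[i]]$source_id)
  }
  # deterministic output: write twice, byte-identical
  path2 <- tempfile(fileext = ".sdf")
  write_sdf(mols, path2)
  expect_identical(readLines(path), readLines(path2))
})
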