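# Fragment library: occurrence counting, first-conformer policy, flat-file
# serialization, byte-offset index, generic ring fallback.

test_that("occurrence counting and thresholds behave as specified", {
  lib3 <- build_library(build_fixture_corpus("benzene", n_copies = 3), min_count = 3)
  expect_equal(lib3$n_fragments, 1L)
  rec <- lookup_exact(lib3, canonical_smiles("c1ccccc1"))
  expect_equal(rec$n_atoms, 6L)

  lib2 <- build_library(build_fixture_corpus("benzene", n_copies = 2), min_count = 3)
  expect_equal(lib2$n_fragments, 0L)

  lib4 <- build_library(build_fixture_corpus("benzene", n_copies = 3), min_count = 4)
  expect_equal(lib4$n_fragments, 0L)

  # biphenyl holds two benzene occurrences per molecule
  libb <- build_library(build_fixture_corpus("biphenyl", n_copies = 3), min_count = 3)
  expect_equal(libb$n_fragments, 1L)
  expect_equal(libb$records[[1]]$occurrence_count, 6L)
  libp <- build_library(build_fixture_corpus("biphenyl", n_copies = 3),
                        min_count = 3, count_per_molecule = TRUE)
  expect_equal(libp$records[[1]]$occurrence_count, 3L)
})

test_that("only the first conformation is stored", {
  clean <- build_library(build_fixture_corpus("benzene", n_copies = 3, jitter_sigma = 0))
  jit <- build_library(build_fixture_corpus("benzene", n_copies = 3,
                                            jitter_sigma = 0.1, seed = 11))
  expect_equal(jit$records[[1]]$coords, clean$records[[1]]$coords)
})

test_that("write -> load round trips every fragment through the flat file", {
  lib <- fixture_library()
  db <- tempfile(); idx <- tempfile()
  write_library(lib, db, idx)
  disk <- load_library(db, idx)
  expect_equal(disk$n_fragments, lib$n_fragments)
  for (key in names(lib$records)) {
    hit <- lookup_exact(disk, key)
    expect_identical(hit$key, key)
    expect_identical(hit$elements, lib$records[[key]]$elements)
    expect_equal(hit$coords, lib$records[[key]]$coords, tolerance = 1e-4)
  }
  # serialized at fixed precision: a second write of the loaded library is
  # bit-exact
  recs <- fragcoord:::library_records(disk)
  lib2 <- structure(list(records = recs, db_path = NULL, index = NULL,
                         n_fragments = length(recs)), class = "fragment_library")
  db2 <- tempfile(); idx2 <- tempfile()
  write_library(lib2, db2, idx2)
  expect_identical(readLines(db), readLines(db2))
})

test_that("indexed lookup is equivalent to a forced linear scan", {
  lib <- fixture_library()
  db <- tempfile(); idx <- tempfile()
  write_library(lib, db, idx)
  disk <- load_library(db, idx)
  set.seed(303)
  random_keys <- replicate(50, paste(sample(c(LETTERS, letters, "(", ")", "1", "="),
                                            12, replace = TRUE), collapse = ""))
  for (key in c(names(lib$records), random_keys)) {
    via_index <- lookup_exact(disk, key)
    via_scan <- lookup_exact(disk, key, use_index = FALSE)
    if (is.null(via_index)) {
      expect_null(via_scan)
    } else {
      expect_identical(via_index$key, via_scan$key)
      expect_identical(via_index$elements, via_scan$elements)
      expect_equal(via_index$coords, via_scan$coords)
    }
  }
})

test_that("loading without an index file gives the same lookups", {
  lib <- fixture_library()
  db <- tempfile(); idx <- tempfile()
  write_library(lib, db, idx)
  noidx <- load_library(db, NULL)
  withidx <- load_library(db, idx)
  expect_setequal(names(noidx$index), names(withidx$index))
  for (key in names(lib$records)) {
    expect_equal(lookup_exact(noidx, key)$coords, lookup_exact(withidx, key)$coords)
  }
})

test_that("an empty library serializes and loads", {
  e <- build_library(list())
  db <- tempfile(); idx <- tempfile()
  write_library(e, db, idx)
  back <- load_library(db, idx)
  expect_equal(back$n_fragments, 0L)
  expect_null(lookup_exact(back, "c1ccccc1"))
})

test_that("malformed records raise errors naming the location", {
  db <- tempfile()
  writeLines(c("c1ccccc1 notanumber", "C 0 0 0"), db)
  expect_error(load_library(db, NULL), "byte offset")
  db2 <- tempfile()
  writeLines(c("c1ccccc1 3", "C 0.0 0.0 0.0", "C 1.0 oops 0.0", "C 2.0 0.0 0.0"), db2)
  expect_error(load_library(db2, NULL), "line|offset")
})

test_that("corpus molecules without coordinates are skipped with a warning", {
  good <- idealized_geometry("benzene")
  bad <- parse_smiles("c1ccncc1")
  expect_warning(lib <- build_library(list(good, bad, good, good)), "no coordinates")
  expect_equal(lib$n_fragments, 1L)
})

test_that("stored coordinates re-keyed through fragment_key reproduce their key", {
  lib <- fixture_library()
  for (key in names(lib$records)) {
    rec <- lib$records[[key]]
    m <- parse_smiles(key)
    m$coords <- rec$coords
    fk <- fragment_key(m, seq_len(n_atoms(m)))
    expect_identical(fk$key, key)
  }
})

test_that("generic ring templates hit, miss, and partially cover as specified", {
  tpl <- ring_templates()
  expect_true(all(vapply(tpl, function(t) fragcoord:::ob_smarts_valid(t$smarts), logical(1))))

  hit <- lookup_generic_ring(tpl, parse_smiles("C1CCCCC1"))
  expect_false(is.null(hit))
  expect_length(hit$mapping, 6L)

  # aromatic heterocycle hits the aromatic pattern, elements come from query
  hp <- lookup_generic_ring(tpl, parse_smiles("c1ccncc1"))
  expect_identical(hp$template$name, "aromatic_6_ring")

  # acyclic fragments miss
  expect_null(lookup_generic_ring(tpl, parse_smiles("CCCCC")))

  # match must cover all ring atoms and bonds: fused bicyclics miss
  expect_null(lookup_generic_ring(tpl, parse_smiles("c1ccc2ccccc2c1")))

  # atoms outside the ring are simply not covered
  hm <- lookup_generic_ring(tpl, parse_smiles("CC1CCCCC1"))
  expect_length(hm$mapping, 6L)
  expect_false(1L %in% hm$mapping)

  # repeated lookups are reproducible
  expect_identical(lookup_generic_ring(tpl, parse_smiles("C1CCCCC1"))$mapping,
                   hit$mapping)
})

test_that("external template files load and match", {
  path <- tempfile()
  hex <- fragcoord:::.polygon_coords(6, 1.54)
  writeLines(c(sprintf("%s %d", "*~1~*~*~*~*~*~1", 6),
               sprintf("%.4f %.4f %.4f", hex[, 1], hex[, 2], hex[, 3]), ""), path)
  tpl <- read_ring_templates(path)
  expect_length(tpl, 1L)
  hit <- lookup_generic_ring(tpl, parse_smiles("C1CCCCC1"))
  expect_false(is.null(hit))
  expect_error(read_ring_templates({
    p <- tempfile(); writeLines("garbage header", p); p
  }), "malformed")
})
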