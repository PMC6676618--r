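# Shared, lazily built test objects (library construction goes through the
# chemistry engine, so build once and reuse).

.test_cache <- new.env(parent = emptyenv())

fixture_library <- function() {
  if (is.null(.test_cache$lib)) {
    .test_cache$lib <- build_library(build_fixture_corpus(n_copies = 3))
  }
  .test_cache$lib
}

fixture_smiles <- function(name) canonical_smiles(idealized_geometry(name))

ring_templates <- function() {
  if (is.null(.test_cache$tpl)) .test_cache$tpl <- generic_ring_templates()
  .test_cache$tpl
}

# bond lengths of a molecule with coordinates
bond_lengths <- function(mol) {
  vapply(seq_len(nrow(mol$bonds)), function(k) {
    sqrt(sum((mol$coords[mol$bonds$a[k], ] - mol$coords[mol$bonds$b[k], ])^2))
  }, numeric(1))
}

vec_angle <- function(u, v) {
  180 / pi * acos(max(-1, min(1, sum(u * v) / sqrt(sum(u * u) * sum(v * v)))))
}

dihedral4 <- function(p) fragcoord:::dihedral(p[1, ], p[2, ], p[3, ], p[4, ])

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
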