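# Generic ring templates: the auxiliary lookup tier. A small built-in set of
# idealized ring geometries stored against generic SMARTS patterns -- planar
# aromatic 5/6-rings, chair cyclohexane, envelope cyclopentane, planar 3/4
# rings, and crown-like 7-18 rings from regular-polygon + pucker rules.
# External template files in the same flat format can be loaded instead.

# planar regular n-gon with given side length, in the xy plane, centered at
# the origin, first vertex on +x
#' @noRd
.polygon_coords <- function(n, side) {
  r <- side / (2 * sin(pi / n))
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(th), r * sin(th), 0)
}

# crown/zigzag n-ring (n even): vertices alternate z = +/- h, with h chosen so
# the bond angle hits `angle_deg` (if reachable) at the given side length
#' @noRd
.crown_coords <- function(n, side, angle_deg = 110.9) {
  stopifnot(n %% 2 == 0)
  chord <- 2 * sin(pi / n)
  angle_at <- function(h) {
    r2 <- side^2 - 4 * h^2
    if (r2 <= 0) return(0)
    r <- sqrt(r2) / chord
    th <- 2 * pi * (0:2) / n
    p <- cbind(r * cos(th), r * sin(th), c(h, -h, h))
    angle_between(p[1, ] - p[2, ], p[3, ] - p[2, ])
  }
  if (angle_at(0) <= angle_deg) {
    h <- 0
  } else {
    h <- stats::uniroot(function(h) angle_at(h) - angle_deg,
                        lower = 1e-6, upper = side / 2 - 1e-6)$root
  }
  r <- sqrt(side^2 - 4 * h^2) / chord
  th <- 2 * pi * (seq_len(n) - 1) / n
  out <- cbind(r * cos(th), r * sin(th), h * (-1)^(seq_len(n) - 1))
  d <- as.matrix(stats::dist(out))
  if (any(d[upper.tri(d)] <= 0.5)) return(.polygon_coords(n, side))
  out
}

# chair 6-ring with given side and ~111 degree angles
#' @noRd
.chair_coords <- function(side = 1.54) .crown_coords(6L, side, 110.9)

# envelope 5-ring: four atoms from the regular pentagon, the fifth lifted out
# of plane keeping its two bond lengths
#' @noRd
.envelope_coords <- function(side = 1.54, flap_deg = 35) {
  p <- .polygon_coords(5L, side)
  p1 <- p[1, ]; p4 <- p[4, ]   # re-seat vertex 5 between vertices 4 and 1
  m <- (p1 + p4) / 2
  u <- unit(p4 - p1)
  rho <- sqrt(side^2 - sum((p4 - p1)^2) / 4)
  centroid <- colMeans(p[1:4, ])
  v <- unit((m - centroid) - sum((m - centroid) * u) * u)
  phi <- .rad(flap_deg)
  p[5, ] <- m + rho * (cos(phi) * v + sin(phi) * c(0, 0, 1))
  p
}

.generic_ring_smarts <- function(n, aromatic = FALSE) {
  if (aromatic) {
    paste0("a1", paste(rep("a", n - 1), collapse = ""), "1")
  } else {
    paste0("*~1", paste(rep("~*", n - 1), collapse = ""), "~1")
  }
}

#' Built-in generic ring templates
#'
#' Idealized ring geometries matched by generic SMARTS patterns, tried in list
#' order: planar aromatic 5- and 6-rings (side 1.39 A), then aliphatic rings
#' of size 3-18 (side 1.54 A: planar 3/4-rings, envelope 5-ring, chair 6-ring,
#' crown-like even rings and planar odd rings beyond that). Elements always
#' come from the query fragment; only coordinates are transferred.
#'
#' @return a list of templates, each `list(name, smarts, coords)` with
#'   `coords` aligned to SMARTS atom order.
#' @export
generic_ring_templates <- function() {
  side_ar <- 1.39; side_al <- 1.54
  tpl <- list(
    list(name = "aromatic_5_ring", smarts = .generic_ring_smarts(5, TRUE),
         coords = .polygon_coords(5, side_ar)),
    list(name = "aromatic_6_ring", smarts = .generic_ring_smarts(6, TRUE),
         coords = .polygon_coords(6, side_ar)),
    list(name = "ring_3", smarts = .generic_ring_smarts(3), coords = .polygon_coords(3, side_al)),
    list(name = "ring_4", smarts = .generic_ring_smarts(4), coords = .polygon_coords(4, side_al)),
    list(name = "ring_5_envelope", smarts = .generic_ring_smarts(5), coords = .envelope_coords(side_al)),
    list(name = "ring_6_chair", smarts = .generic_ring_smarts(6), coords = .chair_coords(side_al))
  )
  for (n in 7:18) {
    coords <- if (n %% 2 == 0) .crown_coords(n, side_al) else .polygon_coords(n, side_al)
    tpl[[length(tpl) + 1L]] <- list(name = sprintf("ring_%d", n),
                                    smarts = .generic_ring_smarts(n), coords = coords)
  }
  tpl
}

#' Read generic ring templates from a flat file
#'
#' Same record layout as the fragment database, but headed by a SMARTS
#' pattern: `<smarts> <n_atoms>` then `n_atoms` lines `<x> <y> <z>`, blank
#' line between records.
#'
#' @param path template file path.
#' @return a list of templates in file order.
#' @export
read_ring_templates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  templates <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    n <- suppressWarnings(as.integer(toks[2]))
    if (length(toks) != 2L || is.na(n)) {
      stop(sprintf("malformed template header at line %d: '%s'", i, lines[i]), call. = FALSE)
    }
    if (!ob_smarts_valid(toks[1])) stop("invalid SMARTS in template file: ", toks[1], call. = FALSE)
    block <- lines[(i + 1L):(i + n)]
    xyz <- t(vapply(strsplit(trimws(block), "[ \t]+"),
                    function(f) as.numeric(f[1:3]), numeric(3)))
    templates[[length(templates) + 1L]] <- list(
      name = sprintf("template_%d", length(templates) + 1L),
      smarts = toks[1], coords = xyz)
    i <- i + n + 1L
  }
  templates
}
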