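# The rigid-fragment geometry database: build from a 3D corpus, serialize to
# a human-auditable flat file plus a key -> byte-offset index, and serve
# exact-key lookups (directly seeking into the flat file, never scanning) with
# a generic-ring SMARTS fallback tier.

#' Build a fragment library from a 3D corpus
#'
#' Every library-eligible fragment occurrence (>= `min_atoms` heavy atoms) in
#' the corpus is counted by canonical key; a fragment enters the library iff
#' its key occurred at least `min_count` times. The stored geometry is the
#' first occurrence in corpus stream order -- later (possibly different)
#' conformations never replace it. Coordinates are re-ordered to the canonical
#' atom order before storage.
#'
#' @param corpus a list of `molgraph` objects with coordinates, or the path to
#'   an SD file.
#' @param min_atoms minimum heavy atoms per stored fragment (default 5).
#' @param min_count minimum occurrence count (default 3).
#' @param count_per_molecule count each key at most once per corpus molecule
#'   (default counts every occurrence).
#' @param amide_rotatable passed to [find_rotatable_bonds()].
#' @return a `fragment_library` (in-memory).
#' @export
build_library <- function(corpus, min_atoms = 5L, min_count = 3L,
                          count_per_molecule = FALSE, amide_rotatable = FALSE) {
  if (is.character(corpus)) corpus <- read_sdf(corpus, perceive_aromaticity = FALSE)
  counts <- new.env(parent = emptyenv())
  first <- new.env(parent = emptyenv())
  order_seen <- character(0)
  for (mi in seq_along(corpus)) {
    mol <- corpus[[mi]]
    if (is.null(mol$coords)) {
      warning("corpus molecule ", mol$source_id %||% mi,
              " has no coordinates; skipped", call. = FALSE)
      next
    }
    frags <- fragment_molecule(mol, min_atoms = min_atoms,
                               amide_rotatable = amide_rotatable)
    seen_here <- character(0)
    for (f in frags) {
      if (!f$eligible) next
      key <- f$key
      if (count_per_molecule && key %in% seen_here) next
      seen_here <- c(seen_here, key)
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      if (is.null(first[[key]])) {
        coords <- mol$coords[f$map, , drop = FALSE]
        d <- as.matrix(stats::dist(coords))
        if (any(d[upper.tri(d)] <= 0.5)) {
          warning("collapsed geometry for fragment ", key, "; occurrence skipped",
                  call. = FALSE)
          counts[[key]] <- counts[[key]] - 1L
          next
        }
        first[[key]] <- list(key = key,
                             elements = mol$atoms$element[f$map],
                             coords = coords,
                             n_atoms = f$n_atoms)
        order_seen <- c(order_seen, key)
      }
    }
  }
  keep <- order_seen[vapply(order_seen, function(k) counts[[k]] >= min_count, logical(1))]
  records <- lapply(keep, function(k) {
    r <- first[[k]]
    r$occurrence_count <- counts[[k]]
    r
  })
  names(records) <- keep
  structure(list(records = records, db_path = NULL, index = NULL,
                 n_fragments = length(records),
                 min_atoms = min_atoms, min_count = min_count),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("<fragment_library> %d fragments (%s)\n", x$n_fragments,
              if (is.null(x$db_path)) "in memory" else x$db_path))
  invisible(x)
}

.format_record <- function(r) {
  c(paste(r$key, r$n_atoms),
    sprintf("%s %.4f %.4f %.4f", r$elements, r$coords[, 1], r$coords[, 2], r$coords[, 3]),
    "")
}

#' Write a fragment library to disk
#'
#' Flat-file format: per record a header line `<canonical_smiles> <n_atoms>`,
#' then one `<element> <x> <y> <z>` line per atom (canonical order, 4 decimal
#' places), records separated by a blank line. The index file holds
#' `<canonical_smiles>\t<byte_offset>` lines pointing at record starts.
#'
#' @param lib a `fragment_library` with in-memory records.
#' @param db_path,index_path output paths.
#' @return `invisible(db_path)`.
#' @export
write_library <- function(lib, db_path, index_path) {
  stopifnot(inherits(lib, "fragment_library"))
  recs <- library_records(lib)
  offsets <- numeric(length(recs))
  pos <- 0
  txt <- character(0)
  for (i in seq_along(recs)) {
    offsets[i] <- pos
    block <- .format_record(recs[[i]])
    txt <- c(txt, block)
    pos <- pos + sum(nchar(block, type = "bytes") + 1L)
  }
  writeLines(txt, db_path, useBytes = TRUE)
  writeLines(sprintf("%s\t%.0f", vapply(recs, `[[`, "", "key"), offsets),
             index_path, useBytes = TRUE)
  invisible(db_path)
}

# All records of a library, in file/insertion order (loads from disk if
# needed -- used by write_library and the linear-scan path).
#' @noRd
library_records <- function(lib) {
  if (!is.null(lib$records)) return(lib$records)
  con <- file(lib$db_path, "rb")
  on.exit(close(con), add = TRUE)
  recs <- list()
  repeat {
    off <- seek(con, NA)
    header <- readLines(con, n = 1L, warn = FALSE)
    if (length(header) == 0L) break
    if (!nzchar(trimws(header))) next
    recs[[length(recs) + 1L]] <- .parse_record(con, header, off, lib$db_path)
  }
  names(recs) <- vapply(recs, `[[`, "", "key")
  recs
}

.parse_record <- function(con, header, offset, path) {
  toks <- strsplit(trimws(header), "[ \t]+")[[1]]
  n <- suppressWarnings(as.integer(toks[2]))
  if (length(toks) != 2L || is.na(n) || n < 1L) {
    stop(sprintf("malformed record header at byte offset %.0f of %s: '%s'",
                 offset, path, header), call. = FALSE)
  }
  lines <- readLines(con, n = n, warn = FALSE)
  if (length(lines) < n) {
    stop(sprintf("truncated record for key '%s' at byte offset %.0f of %s",
                 toks[1], offset, path), call. = FALSE)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(fields, length, integer(1)) != 4L)
  if (length(bad)) {
    stop(sprintf("malformed atom line %d of record '%s' (byte offset %.0f) in %s",
                 bad[1], toks[1], offset, path), call. = FALSE)
  }
  coords <- suppressWarnings(
    cbind(as.numeric(vapply(fields, `[[`, "", 2)),
          as.numeric(vapply(fields, `[[`, "", 3)),
          as.numeric(vapply(fields, `[[`, "", 4))))
  if (!all(is.finite(coords))) {
    stop(sprintf("non-numeric coordinates in record '%s' (byte offset %.0f) in %s",
                 toks[1], offset, path), call. = FALSE)
  }
  list(key = toks[1], elements = vapply(fields, `[[`, "", 1),
       coords = coords, n_atoms = n)
}

#' Load a fragment library from disk
#'
#' With an index file, only the index is read: lookups then seek directly to
#' the record's byte offset. Without one, the flat file is scanned once to
#' rebuild the index (same lookup results, slower startup).
#'
#' @param db_path flat-file database path.
#' @param index_path index path; `NULL` or a missing file triggers the
#'   linear-scan fallback.
#' @return a `fragment_library` (disk-backed).
#' @export
load_library <- function(db_path, index_path = NULL) {
  stopifnot(file.exists(db_path))
  if (!is.null(index_path) && file.exists(index_path)) {
    lines <- readLines(index_path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    toks <- strsplit(lines, "\t", fixed = TRUE)
    index <- vapply(toks, function(t) as.numeric(t[2]), numeric(1))
    names(index) <- vapply(toks, `[[`, "", 1)
  } else {
    # linear-scan fallback: walk the records once, recording their offsets
    con <- file(db_path, "rb")
    on.exit(close(con), add = TRUE)
    index <- numeric(0)
    repeat {
      off <- seek(con, NA)
      header <- readLines(con, n = 1L, warn = FALSE)
      if (length(header) == 0L) break
      if (!nzchar(trimws(header))) next
      rec <- .parse_record(con, header, off, db_path)
      index[rec$key] <- off
    }
  }
  structure(list(records = NULL, db_path = db_path, index = index,
                 n_fragments = length(index)),
            class = "fragment_library")
}

#' Exact-key fragment lookup
#'
#' A hit returns the stored record; for disk-backed libraries the index maps
#' the key to a byte offset and only that record is read. A miss is a value
#' (`NULL`), not an error.
#'
#' @param lib a `fragment_library`.
#' @param key canonical SMILES key (must come from this package's
#'   [canonical_smiles()] / [fragment_key()]).
#' @param use_index set `FALSE` to force a linear scan over all records (used
#'   to verify index equivalence).
#' @return list with `key`, `elements`, `coords`, `n_atoms`, or `NULL`.
#' @export
lookup_exact <- function(lib, key, use_index = TRUE) {
  stopifnot(inherits(lib, "fragment_library"))
  if (!use_index) {
    recs <- library_records(lib)
    for (r in recs) if (r$key == key) return(r[c("key", "elements", "coords", "n_atoms")])
    return(NULL)
  }
  if (!is.null(lib$records)) {
    r <- lib$records[[key]]
    return(if (is.null(r)) NULL else r[c("key", "elements", "coords", "n_atoms")])
  }
  off <- lib$index[key]
  if (is.na(off)) return(NULL)
  con <- file(lib$db_path, "rb")
  on.exit(close(con), add = TRUE)
  seek(con, off)
  header <- readLines(con, n = 1L, warn = FALSE)
  rec <- .parse_record(con, header, off, lib$db_path)
  if (!identical(rec$key, key)) {
    stop(sprintf("index corruption: offset %.0f holds key '%s', expected '%s'",
                 off, rec$key, key), call. = FALSE)
  }
  rec
}

#' Generic-ring template lookup
#'
#' Fallback tier for rigid fragments that miss the exact database: the
#' fragment is tested against each template's SMARTS pattern in list order;
#' the first template whose match covers *all* ring atoms of the fragment
#' wins. Template coordinates are then transferred to the matched atoms
#' (elements are kept from the query); fragment atoms outside the match fall
#' to the rule-based builder.
#'
#' Ring-bond coverage is required as well as ring-atom coverage: a fused
#' polycycle's perimeter must not match a large monocycle template (the fusion
#' bond would become an absurd transannular chord). Templates are ring
#' *cycles*: atom positions adjacent in the pattern (and the closure 1-n) are
#' the template bonds, unless the template carries an explicit `bonds` matrix.
#'
#' @param templates list of ring templates (see [generic_ring_templates()]).
#' @param frag_graph a `molgraph` of the rigid fragment.
#' @return list with `template` and `mapping` (fragment atom index per
#'   template atom position), or `NULL` on miss.
#' @export
lookup_generic_ring <- function(templates, frag_graph) {
  ring_set <- which(frag_graph$atoms$in_ring)
  if (!length(ring_set)) return(NULL)
  rb <- frag_graph$bonds[frag_graph$bonds$in_ring, c("a", "b"), drop = FALSE]
  mb <- mol_to_molblock(frag_graph, use_coords = FALSE)
  for (tpl in templates) {
    n <- nrow(tpl$coords)
    tbonds <- if (!is.null(tpl$bonds)) tpl$bonds else cbind(seq_len(n), c(seq_len(n - 1L) + 1L, 1L))
    tkey <- paste(pmin(tbonds[, 1], tbonds[, 2]), pmax(tbonds[, 1], tbonds[, 2]))
    maps <- ob_smarts_match(mb, tpl$smarts)
    for (m in maps) {
      if (!all(ring_set %in% m)) next
      pa <- match(rb$a, m); pb <- match(rb$b, m)
      if (all(paste(pmin(pa, pb), pmax(pa, pb)) %in% tkey)) {
        return(list(template = tpl, mapping = m))
      }
    }
  }
  NULL
}
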