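# Minimal MDL V2000 molblock / SD file text layer.
#
# This is the interchange format between the package's molecular graph and
# Open Babel, and the on-disk format for 3D structures. A dedicated
# reader/writer is kept here because the pipeline depends on V2000 fields that
# generic SDF containers drop: the atom parity column, bond stereo flag 3
# (explicitly undefined double-bond stereo), M CHG blocks, and byte-exact
# deterministic output.

.legacy_charge <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

#' @noRd
parse_molblock <- function(lines) {
  if (length(lines) == 1L) lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("molblock too short", call. = FALSE)
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || is.na(nbonds)) stop("malformed counts line: ", counts, call. = FALSE)
  if (length(lines) < 4 + natoms + nbonds) stop("truncated molblock", call. = FALSE)

  al <- lines[seq_len(natoms) + 4L]
  atoms <- data.frame(
    x = as.numeric(substr(al, 1, 10)),
    y = as.numeric(substr(al, 11, 20)),
    z = as.numeric(substr(al, 21, 30)),
    element = trimws(substr(al, 32, 34)),
    charge = 0L,
    parity = {
      p <- suppressWarnings(as.integer(substr(al, 40, 42)))
      ifelse(is.na(p), 0L, p)
    },
    stringsAsFactors = FALSE
  )
  legacy <- suppressWarnings(as.integer(substr(al, 37, 39)))
  legacy[is.na(legacy)] <- 0L

  bonds <- if (nbonds > 0L) {
    bl <- lines[seq_len(nbonds) + 4L + natoms]
    data.frame(
      a = as.integer(substr(bl, 1, 3)),
      b = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9)),
      stereo = {
        s <- suppressWarnings(as.integer(substr(bl, 10, 12)))
        ifelse(is.na(s), 0L, s)
      },
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(a = integer(0), b = integer(0), order = integer(0), stereo = integer(0))
  }

  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    for (cl in chg_lines) {
      toks <- as.integer(strsplit(trimws(substring(cl, 7)), "[ ]+")[[1]])
      npairs <- toks[1]
      for (k in seq_len(npairs)) {
        atoms$charge[toks[2 * k]] <- toks[2 * k + 1]
      }
    }
  } else if (any(legacy != 0L)) {
    hit <- legacy != 0L & as.character(legacy) %in% names(.legacy_charge)
    atoms$charge[hit] <- .legacy_charge[as.character(legacy[hit])]
  }

  list(title = lines[1], atoms = atoms, bonds = bonds)
}

# Compose a molblock. coords NULL writes an all-zero 0D block (Open Babel then
# takes stereo from the atom parity column). Deterministic: no timestamps.
#' @noRd
make_molblock <- function(elements, bonds, coords = NULL, charges = NULL,
                          parity = NULL, title = "") {
  n <- length(elements)
  nb <- nrow(bonds)
  if (is.null(coords)) {
    coords <- matrix(0, n, 3)
    dim_tag <- ""
  } else {
    dim_tag <- sprintf("%20s", "3D")
  }
  if (is.null(charges)) charges <- integer(n)
  if (is.null(parity)) parity <- integer(n)
  chiral <- as.integer(any(parity != 0L))
  out <- c(
    title,
    paste0(" fragcoord", dim_tag),
    "",
    sprintf("%3d%3d  0  0%3d  0  0  0  0  0999 V2000", n, nb, chiral),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0%3d  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], elements, parity)
  )
  if (nb > 0L) {
    out <- c(out, sprintf("%3d%3d%3d%3d  0  0  0",
                          bonds$a, bonds$b, bonds$order,
                          if (is.null(bonds$stereo)) integer(nb) else bonds$stereo))
  }
  charged <- which(charges != 0L)
  if (length(charged)) {
    # at most 8 atom/value pairs per M CHG line
    for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
      out <- c(out, paste0("M  CHG", sprintf("%3d", length(grp)),
                           paste0(sprintf("%4d%4d", grp, charges[grp]), collapse = "")))
    }
  }
  paste0(paste(c(out, "M  END"), collapse = "\n"), "\n")
}

# Split the text of an SD file into records, each a list(molblock, data).
#' @noRd
split_sdf_records <- function(lines) {
  if (length(lines) == 1L && grepl("\n", lines, fixed = TRUE)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  }
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0L && length(lines) > 3L) ends <- length(lines) + 1L
  start <- 1L
  records <- list()
  for (e in ends) {
    chunk <- lines[start:(e - 1L)]
    start <- e + 1L
    if (!any(nzchar(chunk))) next
    m_end <- grep("^M  END", chunk)
    if (length(m_end) == 0L) m_end <- length(chunk)
    mol <- chunk[1:m_end[1]]
    rest <- if (m_end[1] < length(chunk)) chunk[(m_end[1] + 1L):length(chunk)] else character(0)
    data <- list()
    tag_at <- grep("^> ", rest)
    for (i in seq_along(tag_at)) {
      tag <- sub("^> *<([^>]*)>.*$", "\\1", rest[tag_at[i]])
      to <- if (i < length(tag_at)) tag_at[i + 1L] - 1L else length(rest)
      vals <- rest[(tag_at[i] + 1L):to]
      vals <- vals[nzchar(vals)]
      data[[tag]] <- paste(vals, collapse = "\n")
    }
    records[[length(records) + 1L]] <- list(molblock = mol, data = data)
  }
  records
}
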