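# Interface to the Open Babel chemistry engine.
#
# All canonicalization, aromaticity perception and SMARTS matching is delegated
# to Open Babel: in-process through ChemmineOB where possible, and through the
# `obabel` command-line tool for InChIKey generation (the InChI library linked
# by ChemmineOB produces non-standard stereo hash blocks; the CLI agrees with
# the reference InChI distribution).

.ob_no_options <- function() data.frame(names = character(0), args = character(0))

.ob_options <- function(...) {
  nm <- c(...)
  if (length(nm) == 0L) return(.ob_no_options())
  data.frame(names = nm, args = rep("", length(nm)))
}

# Convert between text formats, with OB warnings silenced (they go to the C++
# stderr stream and cannot be muffled from R; they are informational only).
ob_convert <- function(from, to, source, options = .ob_no_options()) {
  ChemmineOB::convertFormat(from, to, source, options = options)
}

# SMILES string -> molblock (V2000). gen2D lays the molecule out so that
# declared double-bond stereo is encoded geometrically and undeclared
# stereogenic double bonds are flagged (bond stereo field 3); "h" makes
# hydrogens explicit so per-atom hydrogen counts can be read off. Heavy atoms
# keep their SMILES order; hydrogens are appended.
ob_smiles_to_molblock <- function(smiles) {
  mb <- tryCatch(
    ob_convert("SMI", "MOL", smiles, options = .ob_options("gen2D", "h")),
    error = function(e) ""
  )
  if (!nzchar(mb) || !grepl("V2000", mb, fixed = TRUE)) {
    stop("SMILES parse failure for input: ", smiles, call. = FALSE)
  }
  mb
}

# Canonical SMILES of a molblock. Returns a single string (title stripped).
ob_molblock_to_cansmi <- function(molblock) {
  out <- ob_convert("MOL", "CAN", molblock)
  smi <- strsplit(out, "[ \t\n]", perl = TRUE)[[1]][1]
  if (is.na(smi) || !nzchar(smi)) stop("canonicalization failed", call. = FALSE)
  smi
}

# forEachMol streams SD records and needs the $$$$ terminator a bare molblock
# lacks.
.as_sdf_record <- function(molblock) {
  if (grepl("\\$\\$\\$\\$", molblock)) molblock else paste0(molblock, "$$$$\n")
}

# All unique SMARTS matches of `pattern` against a molblock; a list of integer
# vectors (1-based atom indices, in SMARTS atom order). Empty list on no match.
ob_smarts_match <- function(molblock, pattern) {
  res <- ChemmineOB::forEachMol("SDF", .as_sdf_record(molblock), function(m) {
    sp <- ChemmineOB:::OBSmartsPattern()
    on.exit(ChemmineOB:::delete_OBSmartsPattern(sp), add = TRUE)
    if (!ChemmineOB:::OBSmartsPattern_Init(sp, pattern)) {
      stop("invalid SMARTS pattern: ", pattern, call. = FALSE)
    }
    if (!ChemmineOB:::OBSmartsPattern_Match(sp, m)) return(list())
    ChemmineOB:::OBSmartsPattern_GetUMapList(sp)
  })
  lapply(res[[1]], as.integer)
}

# Validate a SMARTS string without matching it.
ob_smarts_valid <- function(pattern) {
  sp <- ChemmineOB:::OBSmartsPattern()
  on.exit(ChemmineOB:::delete_OBSmartsPattern(sp), add = TRUE)
  isTRUE(ChemmineOB:::OBSmartsPattern_Init(sp, pattern))
}

.obabel_bin <- function() {
  bin <- Sys.which("obabel")
  if (!nzchar(bin)) stop("the `obabel` command-line tool is required for InChIKey generation but was not found on PATH", call. = FALSE)
  bin
}

# InChIKeys via the obabel CLI. `input` is a character vector of SMILES, or a
# path to an SDF file when format = "sdf" (stereo is then perceived from 3D).
# Returns one key per record; NA for records obabel could not convert.
ob_inchikey <- function(input, format = c("smi", "sdf")) {
  format <- match.arg(format)
  bin <- .obabel_bin()
  if (format == "smi") {
    n <- length(input)
    infile <- tempfile(fileext = ".smi")
    on.exit(unlink(infile), add = TRUE)
    writeLines(input, infile)
  } else {
    infile <- input
    n <- length(grep("^\\$\\$\\$\\$", readLines(infile, warn = FALSE)))
  }
  out <- suppressWarnings(system2(bin, c(infile, "-oinchikey"),
                                  stdout = TRUE, stderr = FALSE))
  out <- out[nzchar(out)]
  if (length(out) == n) return(out)
  # A failed record is dropped from obabel's output; recover alignment by
  # converting one record at a time.
  if (format == "smi") {
    vapply(input, function(s) {
      k <- suppressWarnings(system2(bin, c(shQuote(paste0("-:", s)), "-oinchikey"),
                                    stdout = TRUE, stderr = FALSE))
      k <- k[nzchar(k)]
      if (length(k) == 1L) k else NA_character_
    }, character(1), USE.NAMES = FALSE)
  } else {
    vapply(seq_len(n), function(i) {
      k <- suppressWarnings(system2(
        bin, c(infile, "-oinchikey", "-f", i, "-l", i),
        stdout = TRUE, stderr = FALSE))
      k <- k[nzchar(k)]
      if (length(k) == 1L) k else NA_character_
    }, character(1))
  }
}
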