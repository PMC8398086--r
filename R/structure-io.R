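## PDB reading/writing. Parsing and record formatting are delegated to
## bio3d; multi-model files become StructureEnsemble objects.

.bio3d_to_atoms <- function(at) {
  data.frame(
    elety = at$elety,
    elesy = if (!is.null(at$elesy) && !all(is.na(at$elesy)) &&
                !all(trimws(at$elesy) == ""))
              trimws(at$elesy) else substr(trimws(at$elety), 1, 1),
    resid = at$resid,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
}

## quick structural sanity scan so malformed records fail with a line number
.scan_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed ATOM/HETATM record at line ", i,
           ": non-numeric coordinates")
  }
  invisible(TRUE)
}

#' Read a PDB file
#'
#' Fixed-column parse via bio3d. A single-model file yields a
#' [ProteinStructure-class]; a MODEL/ENDMDL multi-model file yields a
#' [StructureEnsemble-class] with frame times `0, dt, 2 dt, ...` ps.
#' The first alternate location is kept; HETATM records are retained and
#' flagged `het = TRUE`.
#'
#' @param path PDB file.
#' @param dt frame spacing in ps for multi-model files (default 20, the
#'   usual trajectory write interval).
#' @return [ProteinStructure-class] or [StructureEnsemble-class].
#' @export
readPDB <- function(path, dt = 20) {
  .scan_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (!is.null(at$alt)) {
    keepAlt <- is.na(at$alt) | at$alt %in% c("", "A", "1")
    at <- at[keepAlt, , drop = FALSE]
  }
  df <- .bio3d_to_atoms(at)
  nModels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  if (nModels <= 1) return(ProteinStructure(df))
  frames <- lapply(seq_len(nModels), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    ## xyz covers all parsed atoms; subset to the altloc-kept rows
    if (!is.null(pdb$atom$alt)) {
      keepAlt <- is.na(pdb$atom$alt) | pdb$atom$alt %in% c("", "A", "1")
      xyz <- xyz[keepAlt, , drop = FALSE]
    }
    f <- df
    f$x <- xyz[, 1]; f$y <- xyz[, 2]; f$z <- xyz[, 3]
    ProteinStructure(f)
  })
  StructureEnsemble(frames, times = (seq_len(nModels) - 1) * dt)
}

#' Write a structure or ensemble to PDB
#'
#' Record formatting is delegated to bio3d; an ensemble is written as
#' MODEL/ENDMDL blocks. Coordinates survive a round trip to the PDB's
#' 3-decimal precision.
#'
#' @param x a [ProteinStructure-class] or [StructureEnsemble-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
  writeOne <- function(st, file) {
    at <- st@atoms
    bio3d::write.pdb(
      file = file,
      xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
      type = ifelse(at$het, "HETATM", "ATOM"),
      resno = at$resno, resid = at$resid, chain = at$chain,
      elety = at$elety, elesy = at$elesy, eleno = seq_len(nrow(at)))
  }
  if (is(x, "ProteinStructure")) {
    writeOne(x, path)
  } else if (is(x, "StructureEnsemble")) {
    blocks <- vapply(seq_along(x@frames), function(m) {
      tmp <- tempfile(fileext = ".pdb")
      on.exit(unlink(tmp), add = TRUE)
      writeOne(x@frames[[m]], tmp)
      lines <- readLines(tmp, warn = FALSE)
      lines <- lines[grepl("^(ATOM  |HETATM|TER)", lines)]
      paste(c(sprintf("MODEL     %4d", m), lines, "ENDMDL"),
            collapse = "\n")
    }, character(1))
    writeLines(c(blocks, "END"), path)
  } else stop("x must be a ProteinStructure or StructureEnsemble")
  invisible(path)
}
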