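## Structure file I/O. GRO is parsed/written natively (fixed-width records,
## coordinates already in nm); PDB goes through bio3d with an A -> nm
## conversion. Orthorhombic boxes only.

#' Read a structure file (GRO or PDB)
#'
#' Positions are returned in nm regardless of the source convention (PDB
#' records in Angstrom are divided by 10). Atom and residue names are kept so
#' selections can be built with [select_atoms()].
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"gro"` or `"pdb"`.
#' @param box Length-3 box override (nm); required for PDB files lacking a
#'   CRYST1 record.
#' @return A list with elements `frame` (a [pf_frame()]) and `atoms` (data
#'   frame with columns `index`, `name`, `resname`, `resid`).
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb"), box = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("gro", "pdb"))
      stop("unsupported format '", format, "': use GRO or PDB")
  }
  switch(format, gro = .read_gro(path), pdb = .read_pdb(path, box))
}

.read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GRO file: fewer than 3 lines")
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || natoms < 1L)
    stop("malformed GRO record at line 2: bad atom count")
  if (length(lines) < 2L + natoms + 1L)
    stop("malformed GRO file: ", natoms, " atoms declared but only ",
         length(lines) - 3L, " atom lines present")
  rows <- lines[3:(2 + natoms)]
  num <- function(s, i) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("malformed GRO record at line ", 2L + bad, ": '", rows[bad], "'")
    }
    v
  }
  x <- num(substr(rows, 21, 28))
  y <- num(substr(rows, 29, 36))
  z <- num(substr(rows, 37, 44))
  atoms <- data.frame(
    index = seq_len(natoms),
    name = trimws(substr(rows, 11, 15)),
    resname = trimws(substr(rows, 6, 10)),
    resid = suppressWarnings(as.integer(trimws(substr(rows, 1, 5)))),
    stringsAsFactors = FALSE
  )
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + natoms]),
                                               "\\s+")[[1]]))
  if (anyNA(boxv) || length(boxv) < 3L)
    stop("malformed GRO record at line ", 3 + natoms, ": bad box line")
  if (length(boxv) > 3L && any(abs(boxv[-(1:3)]) > 1e-9))
    stop("triclinic box not supported: only orthorhombic boxes are handled")
  list(frame = pf_frame(cbind(x, y, z), box = boxv[1:3]), atoms = atoms)
}

.read_pdb <- function(path, box = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("malformed PDB file '", path, "': ",
                                           conditionMessage(e)))
  pos <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z) / 10  # A -> nm
  if (is.null(box)) {
    cr <- grep("^CRYST1", readLines(path, n = 500), value = TRUE)
    if (!length(cr))
      stop("PDB file has no usable CRYST1 record; supply 'box' (nm)")
    v <- suppressWarnings(as.numeric(strsplit(trimws(substr(cr[1], 7, 54)),
                                              "\\s+")[[1]]))
    if (length(v) < 6 || anyNA(v))
      stop("PDB file has no usable CRYST1 record; supply 'box' (nm)")
    if (any(abs(v[4:6] - 90) > 1e-6))
      stop("triclinic box not supported: only orthorhombic boxes are handled")
    box <- v[1:3] / 10
  }
  atoms <- data.frame(
    index = seq_len(nrow(pos)),
    name = trimws(pdb$atom$elety),
    resname = trimws(pdb$atom$resid),
    resid = pdb$atom$resno,
    stringsAsFactors = FALSE
  )
  list(frame = pf_frame(pos, box = box), atoms = atoms)
}

#' Write a frame to a GRO file
#'
#' Coordinates are written with the format's native precision (0.001 nm),
#' which bounds round-trip error at 5e-4 nm per coordinate.
#'
#' @param frame A [pf_frame()].
#' @param path Output path.
#' @param atoms Optional metadata data frame as returned by [read_structure()];
#'   defaults to generic atom names.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, atoms = NULL, title = "poreflux frame") {
  n <- nrow(frame$positions)
  if (is.null(atoms)) {
    atoms <- data.frame(index = seq_len(n), name = "X",
                        resname = "MOL", resid = 1L)
  }
  rows <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  atoms$resid %% 100000L, substr(atoms$resname, 1, 5),
                  substr(atoms$name, 1, 5), atoms$index %% 100000L,
                  frame$positions[, 1], frame$positions[, 2],
                  frame$positions[, 3])
  writeLines(c(title, sprintf("%5d", n), rows,
               sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                       frame$box[3])), path)
  invisible(path)
}

#' Write a frame to a PDB file
#'
#' Thin wrapper over [bio3d::write.pdb()]; positions are converted from nm to
#' Angstrom and the box is emitted as a CRYST1 record.
#'
#' @inheritParams write_gro
#' @return `path`, invisibly.
#' @export
write_pdb <- function(frame, path, atoms = NULL) {
  n <- nrow(frame$positions)
  if (is.null(atoms)) {
    atoms <- data.frame(index = seq_len(n), name = "X",
                        resname = "MOL", resid = 1L)
  }
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(frame$positions)) * 10,
                   resno = atoms$resid, resid = atoms$resname,
                   eleno = atoms$index, elety = atoms$name)
  ## prepend CRYST1 so the box round-trips
  body <- readLines(path)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   frame$box[1] * 10, frame$box[2] * 10, frame$box[3] * 10,
                   90, 90, 90)
  writeLines(c(cryst, body), path)
  invisible(path)
}
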