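## Trajectory I/O and periodic-boundary unwrapping.
##
## Two plain-text dialects are native (and round-trip exactly to their
## printed precision):
##   CSV:  columns frame, time_ns, particle, x, y, z [, box_x, box_y, box_z]
##   XYZ:  natoms / comment "t= <ns> box= <lx> <ly> <lz>" / "EL x y z" rows, nm
## DCD is read through bio3d::read.dcd. XTC has no installed R reader and is
## rejected with a pointer to the text dialects.

#' Read a trajectory file
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"csv"`, `"xyz"` or `"dcd"`.
#' @param box Length-3 box (nm); required for CSV files without box columns
#'   and for DCD files without a cell record.
#' @param dt Frame spacing in ns for DCD files whose header lacks usable
#'   timing (default 0.01 ns, i.e. a 10 ps output stride).
#' @return A [pf_trajectory()] with times in ns, frames in nondecreasing time
#'   order and a constant particle count (violations raise errors).
#' @export
read_trajectory <- function(path, format = c("auto", "csv", "xyz", "dcd", "xtc"),
                            box = NULL, dt = 0.01) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  switch(format,
    csv = .read_traj_csv(path, box),
    xyz = .read_traj_xyz(path),
    dcd = .read_traj_dcd(path, box, dt),
    xtc = stop("unsupported format 'xtc': no installed reader; convert the ",
               "trajectory to the documented CSV or XYZ dialect"),
    stop("unsupported format '", format, "': use CSV, XYZ or DCD")
  )
}

.read_traj_csv <- function(path, box = NULL) {
  tab <- utils::read.csv(path)
  need <- c("frame", "time_ns", "particle", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("malformed CSV trajectory: needs columns ",
         paste(need, collapse = ", "))
  if (nrow(tab) == 0L) stop("empty input: trajectory has zero frames")
  tab <- tab[order(tab$frame, tab$particle), ]
  fr <- unique(tab$frame)
  counts <- table(tab$frame)
  if (length(unique(counts)) != 1L)
    stop("inconsistent particle count across frames: ",
         paste(unique(counts), collapse = ", "))
  np <- as.integer(counts[1])
  nf <- length(fr)
  times <- tab$time_ns[match(fr, tab$frame)]
  if (is.unsorted(times)) stop("frame times must be nondecreasing")
  coords <- array(NA_real_, c(nf, np, 3))
  coords[, , 1] <- matrix(tab$x, nf, np, byrow = TRUE)
  coords[, , 2] <- matrix(tab$y, nf, np, byrow = TRUE)
  coords[, , 3] <- matrix(tab$z, nf, np, byrow = TRUE)
  if (all(c("box_x", "box_y", "box_z") %in% names(tab))) {
    first <- match(fr, tab$frame)
    box <- cbind(tab$box_x[first], tab$box_y[first], tab$box_z[first])
  } else if (is.null(box)) {
    stop("CSV trajectory has no box columns; supply 'box' (nm)")
  }
  pf_trajectory(coords, times, box)
}

.read_traj_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty input: trajectory has zero frames")
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("malformed XYZ record at line ", i, ": bad atom count")
    if (i + 1L + n > length(lines))
      stop("malformed XYZ file: truncated frame at line ", i)
    hdr <- lines[i + 1L]
    tm <- .xyz_field(hdr, "t", 1)
    bx <- .xyz_field(hdr, "box", 3)
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    bad <- which(lengths(rows) < 4L)
    if (length(bad))
      stop("malformed XYZ record at line ", i + 1L + bad[1])
    pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(pos)) stop("malformed XYZ coordinates in frame starting line ", i)
    frames[[length(frames) + 1L]] <- pf_frame(pos, box = bx, time = tm)
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("empty input: trajectory has zero frames")
  as_trajectory(frames)
}

.xyz_field <- function(hdr, key, n) {
  m <- regmatches(hdr, regexec(paste0(key, "=\\s*(\\S+(\\s+\\S+){",
                                      n - 1, "})"), hdr))[[1]]
  if (length(m) < 2) stop("malformed XYZ comment line (needs '", key, "='): ",
                          hdr)
  as.numeric(strsplit(m[2], "\\s+")[[1]])
}

.read_traj_dcd <- function(path, box = NULL, dt = 0.01) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)  # frames x 3N, Angstrom
  nf <- nrow(xyz)
  np <- ncol(xyz) / 3L
  coords <- array(NA_real_, c(nf, np, 3))
  coords[, , 1] <- xyz[, seq(1, 3 * np, 3)] / 10
  coords[, , 2] <- xyz[, seq(2, 3 * np, 3)] / 10
  coords[, , 3] <- xyz[, seq(3, 3 * np, 3)] / 10
  if (is.null(box))
    stop("DCD trajectories need an explicit 'box' (nm)")
  pf_trajectory(coords, times = (seq_len(nf) - 1) * dt, box = box)
}

#' Write a trajectory to the CSV dialect
#'
#' Columns: `frame, time_ns, particle, x, y, z, box_x, box_y, box_z`, one row
#' per particle per frame, coordinates in nm, times in ns.
#'
#' @param traj A [pf_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  nf <- n_frames(traj); np <- n_particles(traj)
  tab <- data.frame(
    frame = rep(seq_len(nf), each = np),
    time_ns = rep(traj$times, each = np),
    particle = rep(seq_len(np), nf),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3])),
    box_x = rep(traj$box[, 1], each = np),
    box_y = rep(traj$box[, 2], each = np),
    box_z = rep(traj$box[, 3], each = np)
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory to the XYZ dialect
#'
#' @inheritParams write_trajectory_csv
#' @param digits Printed coordinate precision (decimal places, nm).
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path, digits = 6) {
  nf <- n_frames(traj); np <- n_particles(traj)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("X %.", digits, "f %.", digits, "f %.", digits, "f")
  for (i in seq_len(nf)) {
    writeLines(c(
      sprintf("%d", np),
      sprintf("t= %.9g box= %.9g %.9g %.9g", traj$times[i],
              traj$box[i, 1], traj$box[i, 2], traj$box[i, 3]),
      sprintf(fmt, traj$coords[i, , 1], traj$coords[i, , 2],
              traj$coords[i, , 3])
    ), con)
  }
  invisible(path)
}

#' Unwrap particle paths along the channel axis
#'
#' Makes axial (z) coordinates continuous across the periodic boundary by
#' minimum-image accumulation, so that plane crossings can be counted.
#' Non-axial coordinates are untouched. The per-frame axial displacement of
#' every selected particle must be below half the box edge; an apparent jump
#' of exactly half a box edge is ambiguous and raises an error advising
#' denser output sampling.
#'
#' @param traj A [pf_trajectory()].
#' @param sel Optional [selection()]; default unwraps all particles.
#' @return A new [pf_trajectory()] with continuous axial coordinates (which
#'   may leave the primary box).
#' @seealso [wrap_axis()] for the inverse.
#' @export
unwrap_axis <- function(traj, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(n_particles(traj)) else sel$indices
  z <- traj$coords[, idx, 3, drop = FALSE]
  dim(z) <- c(n_frames(traj), length(idx))
  nf <- nrow(z)
  if (nf > 1L) {
    L <- traj$box[-1, 3]  # box of the later frame of each step
    dz <- z[-1, , drop = FALSE] - z[-nf, , drop = FALSE]
    dz_img <- dz - round(dz / L) * L
    if (any(abs(abs(dz_img) - L / 2) < 1e-9))
      stop("ambiguous axial displacement of half a box edge between frames; ",
           "use a denser trajectory output stride")
    cs <- apply(dz_img, 2, cumsum)
    if (is.null(dim(cs))) dim(cs) <- c(1L, ncol(z))
    zc <- rbind(z[1, ], sweep(cs, 2, z[1, ], "+"))
    traj$coords[, idx, 3] <- zc
  }
  traj
}

#' Rewrap axial coordinates into the primary box
#'
#' Inverse of [unwrap_axis()]: folds z back into `[0, box_z)` per frame.
#'
#' @inheritParams unwrap_axis
#' @return A [pf_trajectory()] with axial coordinates inside the box.
#' @export
wrap_axis <- function(traj, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(n_particles(traj)) else sel$indices
  z <- traj$coords[, idx, 3, drop = FALSE]
  dim(z) <- c(n_frames(traj), length(idx))
  L <- traj$box[, 3]
  traj$coords[, idx, 3] <- z - floor(z / L) * L
  traj
}
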