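## Uniform frame/trajectory model consumed by every analysis module.
## Coordinates in nm, times in ns, orthorhombic boxes only.

#' Construct a single coordinate frame
#'
#' A frame holds the positions of all particles at one time point together
#' with the orthorhombic periodic box.
#'
#' @param positions Numeric matrix, one row per particle, columns x, y, z (nm).
#' @param box Numeric length-3 vector of box edge lengths (nm); all > 0.
#' @param time Time of the frame (ns).
#' @return An object of class `pf_frame` with elements `positions`, `box`,
#'   `time`.
#' @examples
#' fr <- pf_frame(matrix(runif(9), 3, 3), box = c(10, 10, 10))
#' @export
pf_frame <- function(positions, box, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("'positions' must have 3 columns (x, y, z)")
  storage.mode(positions) <- "double"
  if (!all(is.finite(positions)))
    stop("all coordinates must be finite")
  box <- as.numeric(box)
  if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0))
    stop("'box' must be 3 positive finite edge lengths (orthorhombic)")
  if (!is.finite(time)) stop("'time' must be finite")
  structure(list(positions = positions, box = box, time = as.numeric(time)),
            class = "pf_frame")
}

#' @export
print.pf_frame <- function(x, ...) {
  cat(sprintf("<pf_frame> %d particles, t = %g ns, box = %s nm\n",
              nrow(x$positions), x$time,
              paste(signif(x$box, 6), collapse = " x ")))
  invisible(x)
}

#' Construct a trajectory
#'
#' A trajectory is a time-ordered sequence of frames with a constant particle
#' count. Coordinates are stored as an array `[frame, particle, xyz]`.
#'
#' @param coords Numeric array of dimension `c(n_frames, n_particles, 3)` (nm).
#' @param times Numeric vector of frame times (ns), nondecreasing.
#' @param box Either a length-3 vector (constant box) or an
#'   `n_frames x 3` matrix of per-frame edge lengths (nm).
#' @return An object of class `pf_trajectory`.
#' @seealso [as_trajectory()] to build one from a list of [pf_frame()]s.
#' @export
pf_trajectory <- function(coords, times, box) {
  coords <- unclass(coords)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("'coords' must be an [frame, particle, xyz] array")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  nf <- dim(coords)[1]
  if (nf < 1L) stop("empty input: a trajectory needs at least one frame")
  times <- as.numeric(times)
  if (length(times) != nf || !all(is.finite(times)))
    stop("'times' must give one finite time per frame")
  if (is.unsorted(times))
    stop("frame times must be nondecreasing")
  if (is.matrix(box)) {
    if (nrow(box) != nf || ncol(box) != 3L) stop("per-frame 'box' must be n_frames x 3")
  } else {
    box <- matrix(as.numeric(box), nrow = nf, ncol = 3, byrow = TRUE)
  }
  if (!all(is.finite(box)) || any(box <= 0))
    stop("'box' must be positive finite edge lengths (orthorhombic)")
  structure(list(coords = coords, times = times, box = box),
            class = "pf_trajectory")
}

#' Assemble a trajectory from a list of frames
#'
#' @param frames List of [pf_frame()] objects with identical particle counts.
#' @return A [pf_trajectory()].
#' @export
as_trajectory <- function(frames) {
  if (length(frames) == 0L) stop("empty input: no frames")
  np <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(np)) != 1L)
    stop("inconsistent particle count across frames: ",
         paste(unique(np), collapse = ", "))
  nf <- length(frames)
  coords <- array(NA_real_, c(nf, np[1], 3))
  for (i in seq_len(nf)) coords[i, , ] <- frames[[i]]$positions
  pf_trajectory(coords,
                times = vapply(frames, `[[`, numeric(1), "time"),
                box = do.call(rbind, lapply(frames, `[[`, "box")))
}

#' Number of frames / particles in a trajectory
#' @param traj A [pf_trajectory()].
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_particles <- function(traj) dim(traj$coords)[2]

#' Extract one frame from a trajectory
#' @param traj A [pf_trajectory()].
#' @param i Frame index (1-based).
#' @return A [pf_frame()].
#' @export
frame_at <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  pos <- traj$coords[i, , , drop = FALSE]
  dim(pos) <- dim(traj$coords)[2:3]
  pf_frame(pos, box = traj$box[i, ], time = traj$times[i])
}

#' @export
print.pf_trajectory <- function(x, ...) {
  cat(sprintf("<pf_trajectory> %d frames x %d particles, t = [%g, %g] ns\n",
              n_frames(x), n_particles(x), min(x$times), max(x$times)))
  invisible(x)
}

#' Total sampled duration of a trajectory (ns)
#' @param traj A [pf_trajectory()].
#' @return `max(times) - min(times)`.
#' @export
duration <- function(traj) max(traj$times) - min(traj$times)
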