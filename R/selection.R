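## Selections and channel geometry: the only handles downstream analyses use.

.pf_roles <- c("water-oxygen", "lipid-C2", "lipid-tail-carbon",
               "protein-backbone", "ion")

#' Define a particle selection
#'
#' A named set of particle indices with a role that determines which analyses
#' accept it (e.g. only `water-oxygen` selections are counted as permeating
#' water; water is represented by its oxygen atom throughout).
#'
#' @param indices Integer vector of 1-based particle indices, unique.
#' @param role One of `"water-oxygen"`, `"lipid-C2"`, `"lipid-tail-carbon"`,
#'   `"protein-backbone"`, `"ion"`.
#' @param name Label for the selection.
#' @param n_particles Optional total particle count for bounds checking.
#' @return An object of class `pf_selection`.
#' @export
selection <- function(indices, role, name = role, n_particles = NULL) {
  role <- match.arg(role, .pf_roles)
  indices <- as.integer(indices)
  if (anyNA(indices) || any(indices < 1L))
    stop("selection indices must be positive integers (1-based)")
  if (anyDuplicated(indices))
    stop("selection indices must be unique")
  if (!is.null(n_particles) && any(indices > n_particles))
    stop("selection index exceeds particle count (", n_particles, ")")
  structure(list(name = name, indices = indices, role = role),
            class = "pf_selection")
}

#' @export
print.pf_selection <- function(x, ...) {
  cat(sprintf("<pf_selection> '%s' (%s): %d particles\n",
              x$name, x$role, length(x$indices)))
  invisible(x)
}

#' Build a selection from atom metadata
#'
#' Convenience constructor matching atom/residue names in the metadata table
#' returned by [read_structure()].
#'
#' @param atoms Data frame with columns `name` (atom name) and `resname`.
#' @param atom_name Atom name(s) to match (e.g. `"OW"`, `"C2"`); the marker
#'   atom is configurable rather than hard-coded because naming conventions
#'   differ between force fields.
#' @param resname Optional residue name filter.
#' @inheritParams selection
#' @return A `pf_selection`.
#' @export
select_atoms <- function(atoms, atom_name, role, resname = NULL,
                         name = paste(atom_name, collapse = "+")) {
  keep <- atoms$name %in% atom_name
  if (!is.null(resname)) keep <- keep & atoms$resname %in% resname
  selection(which(keep), role = role, name = name, n_particles = nrow(atoms))
}

#' Define the channel geometry
#'
#' A cylindrical channel through the membrane: an axis (currently the +z
#' direction), a radius, and entry/exit planes at axial offsets `z_lo` and
#' `z_hi` from the axis origin. By convention the axis origin sits at the
#' channel center so the membrane midplane is z = 0.
#'
#' @param radius Channel radius (nm), > 0.
#' @param z_lo,z_hi Entry/exit plane offsets along the axis (nm), `z_lo < z_hi`.
#' @param origin Axis origin (3-vector, nm).
#' @param axis Axis direction; only the +z axis `c(0, 0, 1)` is supported.
#' @return An object of class `pf_channel`.
#' @export
channel_geometry <- function(radius, z_lo, z_hi, origin = c(0, 0, 0),
                             axis = c(0, 0, 1)) {
  if (!is.numeric(radius) || radius <= 0) stop("'radius' must be > 0")
  if (!(z_lo < z_hi)) stop("'z_lo' must be < 'z_hi'")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("'origin' must be a finite 3-vector")
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  if (!isTRUE(all.equal(axis, c(0, 0, 1))))
    stop("only the +z channel axis is supported")
  structure(list(origin = origin, axis = axis, radius = as.numeric(radius),
                 z_lo = as.numeric(z_lo), z_hi = as.numeric(z_hi)),
            class = "pf_channel")
}

#' @export
print.pf_channel <- function(x, ...) {
  cat(sprintf("<pf_channel> radius %g nm, planes z = [%g, %g] nm, origin (%s)\n",
              x$radius, x$z_lo, x$z_hi, paste(x$origin, collapse = ", ")))
  invisible(x)
}

#' Read an analysis configuration file
#'
#' Parses a YAML configuration defining selections, channel geometry, pressure
#' regions, bin widths and seeds, and instantiates the corresponding objects.
#' Recognised top-level keys: `channel` (radius, z_lo, z_hi, origin),
#' `selections` (list of name: \{indices, role\}), `synthetic`
#' (passed to [synthetic_spec()]), plus arbitrary scalar parameters returned
#' verbatim.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `channel` (`pf_channel` or NULL), `selections`
#'   (named list of `pf_selection`), `synthetic` (`pf_synth_spec` or NULL),
#'   and `params` (everything else).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(channel = NULL, selections = list(), synthetic = NULL,
              params = cfg)
  if (!is.null(cfg$channel)) {
    out$channel <- do.call(channel_geometry, cfg$channel)
    out$params$channel <- NULL
  }
  if (!is.null(cfg$selections)) {
    out$selections <- lapply(names(cfg$selections), function(nm) {
      s <- cfg$selections[[nm]]
      selection(s$indices, role = s$role, name = nm)
    })
    names(out$selections) <- names(cfg$selections)
    out$params$selections <- NULL
  }
  if (!is.null(cfg$synthetic)) {
    out$synthetic <- do.call(synthetic_spec, cfg$synthetic)
    out$params$synthetic <- NULL
  }
  out
}

## internal: axial + radial coordinates of selected particles, relative to
## an origin, as nf x n matrices. Used by permeation and profiles.
.axial_radial <- function(traj, indices, origin = c(0, 0, 0)) {
  d <- c(dim(traj$coords)[1], length(indices))
  x <- traj$coords[, indices, 1, drop = FALSE] - origin[1]
  y <- traj$coords[, indices, 2, drop = FALSE] - origin[2]
  z <- traj$coords[, indices, 3, drop = FALSE] - origin[3]
  dim(x) <- dim(y) <- dim(z) <- d
  list(z = z, rho2 = x^2 + y^2)
}
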