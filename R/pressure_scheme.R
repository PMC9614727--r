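## Region-based constant-force pressure method.
##
## The water layer of a periodic slab system is partitioned into three
## z-regions, with region III isolated from the two faces of the membrane by
## regions I and II. A constant axial force f on every water molecule in
## region III (thickness d, membrane area A) generates a pressure difference
## between regions I and II:
##
##   dP = n f / A = f d / v_W,    n = A d / v_W,    dmu = f d = dP v_W,
##
## with v_W the average volume of one water molecule. These identities are
## exact arithmetic and are implemented (and tested) as such; no dynamics are
## integrated here.

#' Define a region-based pressure scheme
#'
#' @param region_I,region_II,region_III z-intervals `c(lo, hi)` in nm.
#'   Membership uses half-open intervals `[lo, hi)` so the regions form a
#'   partition with no double counting. The regions must be disjoint, with
#'   region III isolated from the membrane faces by regions I and II.
#' @param A Membrane cross-sectional area, nm^2 (> 0).
#' @param f Per-molecule axial force, kJ mol^-1 nm^-1.
#' @param v_W Average volume of one water molecule, nm^3 (default
#'   `pf_constants$v_W` = 0.0301, bulk water at 300 K and 1 bar).
#' @param restraints Optional named list recording positional-restraint
#'   metadata (e.g. spring constants for protein/lipid/wall atoms). Stored
#'   verbatim as configuration bookkeeping; no dynamics are integrated.
#' @return An object of class `pf_scheme` with the derived thickness
#'   `d = diff(region_III)` and expected occupancy `n = A d / v_W`.
#' @export
pressure_scheme <- function(region_I, region_II, region_III, A, f,
                            v_W = pf_constants$v_W, restraints = NULL) {
  chk <- function(r, nm) {
    r <- as.numeric(r)
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      stop("'", nm, "' must be a finite interval c(lo, hi) with lo < hi")
    r
  }
  region_I <- chk(region_I, "region_I")
  region_II <- chk(region_II, "region_II")
  region_III <- chk(region_III, "region_III")
  regs <- list(region_I, region_II, region_III)
  for (i in 1:2) for (j in (i + 1):3) {
    if (max(regs[[i]][1], regs[[j]][1]) < min(regs[[i]][2], regs[[j]][2]))
      stop("pressure regions must be disjoint")
  }
  if (A <= 0) stop("'A' must be > 0")
  if (v_W <= 0) stop("'v_W' must be > 0")
  d <- region_III[2] - region_III[1]
  structure(list(region_I = region_I, region_II = region_II,
                 region_III = region_III, d = d, A = as.numeric(A),
                 v_W = as.numeric(v_W), f = as.numeric(f),
                 n = A * d / v_W, restraints = restraints),
            class = "pf_scheme")
}

#' @export
print.pf_scheme <- function(x, ...) {
  dp <- pressure_from_force(x$f, d = x$d, v_W = x$v_W, A = x$A)
  cat(sprintf(paste0("<pf_scheme> region III [%g, %g) nm (d = %g nm), ",
                     "A = %g nm^2, v_W = %g nm^3\n  f = %g kJ/mol/nm (%g pN),",
                     " n = %g waters, dP = %g MPa\n"),
              x$region_III[1], x$region_III[2], x$d, x$A, x$v_W, x$f,
              x$f * pf_constants$pN_per_kJmol_nm, x$n, dp$delta_P))
  invisible(x)
}

#' Per-molecule force required for a target pressure difference
#'
#' Inverts the scheme identity: `f = delta_P * v_W / d` (with MPa.nm^3
#' converted to kJ/mol). Linear in `delta_P`, and `f = 0` at `delta_P = 0`.
#'
#' @param delta_P Target pressure difference, MPa.
#' @param d Thickness of the forced region III, nm (> 0). The reference
#'   setting is an 8 nm thick layer.
#' @param v_W Average volume of one water molecule, nm^3 (> 0).
#' @return Force per molecule, kJ mol^-1 nm^-1.
#' @examples
#' force_for_pressure(80, d = 8)   # ~0.181 kJ/mol/nm
#' @export
force_for_pressure <- function(delta_P, d = 8, v_W = pf_constants$v_W) {
  if (!all(is.finite(delta_P))) stop("'delta_P' must be finite")
  if (d <= 0) stop("'d' must be > 0")
  if (v_W <= 0) stop("'v_W' must be > 0")
  delta_P * v_W * pf_constants$kJmol_per_MPa_nm3 / d
}

#' Pressure difference generated by a per-molecule force
#'
#' Computes `delta_P = n f / A` (or, equivalently and exactly,
#' `f d / v_W`) and the chemical potential difference `delta_mu = f d`.
#' Supply either `n` with `A`, or `d` with `v_W` and `A`; when all are given
#' `n` must satisfy `n = A d / v_W`.
#'
#' @param f Per-molecule force, kJ mol^-1 nm^-1.
#' @param n Number of water molecules in region III.
#' @param A Membrane area, nm^2 (> 0).
#' @param d Region III thickness, nm.
#' @param v_W Water molecular volume, nm^3.
#' @return A list of class `pf_pressure_drop` with `delta_P` (MPa) and
#'   `delta_mu` (kJ/mol); signs follow the sign of `f`.
#' @export
pressure_from_force <- function(f, n = NULL, A = NULL, d = NULL,
                                v_W = pf_constants$v_W) {
  if (!is.null(A) && A <= 0) stop("'A' must be > 0")
  if (is.null(n)) {
    if (is.null(d) || is.null(A)) stop("supply either 'n' (with 'A') or 'd' and 'A'")
    if (d <= 0) stop("'d' must be > 0")
    if (v_W <= 0) stop("'v_W' must be > 0")
    n <- A * d / v_W
  } else if (is.null(A)) {
    stop("'A' is required with 'n'")
  }
  if (is.null(d)) d <- n * v_W / A
  ## n f / A has units kJ/mol/nm^3; divide by (kJ/mol per MPa nm^3) -> MPa
  delta_P <- n * f / A / pf_constants$kJmol_per_MPa_nm3
  delta_mu <- f * d
  structure(list(delta_P = delta_P, delta_mu = delta_mu),
            class = "pf_pressure_drop")
}

#' @export
print.pf_pressure_drop <- function(x, ...) {
  cat(sprintf("<pf_pressure_drop> dP = %g MPa, dmu = %g kJ/mol\n",
              x$delta_P, x$delta_mu))
  invisible(x)
}

#' Evaluate the scheme on one frame
#'
#' Returns the constant force vector `(0, 0, f)` for every selected water
#' whose z lies in region III (half-open interval), zero for all other
#' particles, plus the instantaneous region III occupancy for diagnostics.
#' An empty region III occupancy yields a warning (the pressure is undefined
#' for that frame), not an error.
#'
#' @param frame A [pf_frame()].
#' @param waters A [selection()] with role `"water-oxygen"`.
#' @param scheme A [pressure_scheme()]. Region III must lie inside the box.
#' @return A list with `forces` (n_particles x 3 matrix, kJ mol^-1 nm^-1)
#'   and `n_inst` (count of selected particles in region III).
#' @export
apply_scheme <- function(frame, waters, scheme) {
  stopifnot(inherits(frame, "pf_frame"), inherits(waters, "pf_selection"),
            inherits(scheme, "pf_scheme"))
  if (waters$role != "water-oxygen")
    stop("'waters' must have role 'water-oxygen'")
  r3 <- scheme$region_III
  if (scheme$d > frame$box[3])
    stop("region III is thicker than the box along z")
  z <- frame$positions[waters$indices, 3]
  inIII <- z >= r3[1] & z < r3[2]
  forces <- matrix(0, nrow(frame$positions), 3)
  forces[waters$indices[inIII], 3] <- scheme$f
  n_inst <- sum(inIII)
  if (n_inst == 0L)
    warning("no selected waters in region III: pressure undefined this frame")
  list(forces = forces, n_inst = n_inst)
}
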