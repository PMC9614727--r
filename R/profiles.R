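## Structural-stability profiles: radial bilayer thickness, axial density,
## hydrocarbon-chain elongation, backbone RMSD.
##
## "Standard error" throughout is the block-decorrelated SE of the mean over
## frames: the trajectory is cut into `blocks` (default 5) contiguous blocks,
## the statistic is computed per block, and the SE of the block means is
## reported.

.block_se <- function(block_vals) {
  v <- block_vals[is.finite(block_vals)]
  if (length(v) < 2L) return(NA_real_)
  stats::sd(v) / sqrt(length(v))
}

.frame_blocks <- function(nf, blocks) {
  sort(rep_len(seq_len(blocks), nf))
}

## optional per-frame recentring on a reference selection's centroid, so that
## profiles are measured around the protein (membrane midplane at z = 0)
.center_traj <- function(traj, center) {
  if (is.null(center)) return(traj)
  idx <- center$indices
  for (k in 1:3) {
    cen <- rowMeans(traj$coords[, idx, k, drop = FALSE])
    traj$coords[, , k] <- traj$coords[, , k] - cen
  }
  traj
}

#' Radial bilayer-thickness profile
#'
#' Transforms the leaflet marker atoms (the lipid C2 carbon separating the
#' hydrophilic head from the hydrophobic tails) to cylindrical coordinates
#' (rho, z) about the channel axis, and reports the per-bin mean axial
#' position of each leaflet and the local thickness
#' `h(rho) = mean z_upper - mean z_lower`, pooled over frames and molecules.
#' Empty bins are flagged (`occupied = FALSE`), not zero-filled.
#'
#' @param traj A [pf_trajectory()].
#' @param c2_upper,c2_lower [selection()]s of the upper/lower leaflet C2
#'   markers (role `"lipid-C2"`), nonempty.
#' @param origin Axis origin (3-vector, nm).
#' @param breaks Radial bin edges (nm), monotone increasing; default 0.25 nm
#'   bins over `[0, rho_max]`.
#' @param rho_max Outer radius used for the default bins (nm).
#' @param blocks Blocks for the standard error.
#' @param se_method `"block"` (default): SE of per-block thickness means,
#'   robust to frame-to-frame correlation. `"iid"`: SE from the per-sample
#'   scatter, `sqrt(var_up/n_up + var_lo/n_lo)`; well calibrated when marker
#'   positions are independent across frames (as in the synthetic shell).
#' @param center Optional selection (e.g. protein backbone) whose centroid is
#'   moved to the origin each frame before binning.
#' @return Data frame of class `pf_thickness`: `rho_lo`, `rho_hi`, `rho_mid`,
#'   `z_upper`, `z_lower`, `thickness`, `se`, `n_upper`, `n_lower`,
#'   `occupied`.
#' @export
radial_thickness <- function(traj, c2_upper, c2_lower, origin = c(0, 0, 0),
                             breaks = NULL, rho_max = 4, blocks = 5,
                             se_method = c("block", "iid"), center = NULL) {
  se_method <- match.arg(se_method)
  if (length(c2_upper$indices) == 0L || length(c2_lower$indices) == 0L)
    stop("leaflet selections must be nonempty")
  if (is.null(breaks)) breaks <- seq(0, rho_max, by = 0.25)
  if (is.unsorted(breaks, strictly = TRUE)) stop("'breaks' must be monotone")
  traj <- .center_traj(traj, center)
  nf <- n_frames(traj)
  fb <- .frame_blocks(nf, blocks)
  nb <- length(breaks) - 1L

  leaflet <- function(sel) {
    ar <- .axial_radial(traj, sel$indices, origin)
    rho <- sqrt(ar$rho2)
    bin <- findInterval(rho, breaks, rightmost.closed = TRUE)
    keep <- bin >= 1L & bin <= nb
    blk <- matrix(fb, nf, length(sel$indices))
    list(z = ar$z[keep], bin = bin[keep], blk = blk[keep])
  }
  up <- leaflet(c2_upper)
  lo <- leaflet(c2_lower)

  mean_by <- function(l) {
    s <- tapply(l$z, factor(l$bin, levels = seq_len(nb)), mean)
    as.numeric(s)
  }
  z_up <- mean_by(up)
  z_lo <- mean_by(lo)
  n_up <- as.numeric(table(factor(up$bin, levels = seq_len(nb))))
  n_lo <- as.numeric(table(factor(lo$bin, levels = seq_len(nb))))

  se <- if (se_method == "block") {
    ## per-block thickness means
    vapply(seq_len(nb), function(b) {
      hb <- vapply(seq_len(blocks), function(k) {
        zu <- up$z[up$bin == b & up$blk == k]
        zl <- lo$z[lo$bin == b & lo$blk == k]
        if (!length(zu) || !length(zl)) return(NA_real_)
        mean(zu) - mean(zl)
      }, numeric(1))
      .block_se(hb)
    }, numeric(1))
  } else {
    vapply(seq_len(nb), function(b) {
      zu <- up$z[up$bin == b]
      zl <- lo$z[lo$bin == b]
      if (length(zu) < 2L || length(zl) < 2L) return(NA_real_)
      sqrt(stats::var(zu) / length(zu) + stats::var(zl) / length(zl))
    }, numeric(1))
  }

  out <- data.frame(
    rho_lo = breaks[-length(breaks)], rho_hi = breaks[-1],
    rho_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    z_upper = z_up, z_lower = z_lo,
    thickness = z_up - z_lo, se = se,
    n_upper = n_up, n_lower = n_lo,
    occupied = n_up > 0 & n_lo > 0
  )
  class(out) <- c("pf_thickness", "data.frame")
  out
}

#' Axial density profile
#'
#' Bins selected particles along z and reports the per-bin density averaged
#' over frames: number density `count / (A * bin width)` in nm^-3, or mass
#' density in g cm^-3 when a molar mass is given.
#'
#' @param traj A [pf_trajectory()].
#' @param sel A [selection()] (e.g. water oxygens or ions). An empty
#'   selection yields an all-zero profile.
#' @param breaks z bin edges (nm); default 0.1 nm bins spanning `z_range`.
#' @param A Cross-sectional area of the analysed column, nm^2 (> 0).
#' @param mass Optional molar mass per particle (g/mol) for mass density.
#' @param z_range Range used for default bins.
#' @param origin Axis origin.
#' @param blocks Blocks for the standard error.
#' @param center Optional centring selection (see [radial_thickness()]).
#' @return Data frame of class `pf_density`: `z_lo`, `z_hi`, `z_mid`,
#'   `density` (nm^-3 or g cm^-3), `se`, `species`. The number-density
#'   profile satisfies sum(density * A * bin width) = mean count per frame.
#' @export
axial_density <- function(traj, sel, breaks = NULL, A, mass = NULL,
                          z_range = c(-8, 8), origin = c(0, 0, 0),
                          blocks = 5, center = NULL) {
  if (missing(A) || A <= 0) stop("'A' must be > 0")
  if (is.null(breaks)) breaks <- seq(z_range[1], z_range[2], by = 0.1)
  if (is.unsorted(breaks, strictly = TRUE)) stop("'breaks' must be monotone")
  dz <- diff(breaks)
  if (any(dz <= 0)) stop("zero bin width")
  nb <- length(breaks) - 1L
  traj <- .center_traj(traj, center)
  nf <- n_frames(traj)
  fb <- .frame_blocks(nf, blocks)

  if (length(sel$indices) == 0L) {
    counts <- matrix(0, nf, nb)
  } else {
    ar <- .axial_radial(traj, sel$indices, origin)
    bin <- findInterval(ar$z, breaks, rightmost.closed = TRUE)
    bin[bin < 1L | bin > nb] <- NA_integer_
    dim(bin) <- dim(ar$z)
    counts <- t(vapply(seq_len(nf), function(i)
      tabulate(bin[i, ], nbins = nb), numeric(nb)))
  }
  dens_f <- sweep(counts, 2, A * dz, "/")          # nm^-3, per frame
  unit <- "nm^-3"
  if (!is.null(mass)) {
    ## amu/nm^3 -> g/cm^3: m[g/mol]/N_A g per 1e-21 cm^3
    dens_f <- dens_f * mass * 1e21 / pf_constants$N_A
    unit <- "g cm^-3"
  }
  dens <- colMeans(dens_f)
  se <- vapply(seq_len(nb), function(b)
    .block_se(vapply(seq_len(blocks), function(k)
      mean(dens_f[fb == k, b]), numeric(1))), numeric(1))
  out <- data.frame(
    z_lo = breaks[-length(breaks)], z_hi = breaks[-1],
    z_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    density = dens, se = se, species = sel$name
  )
  attr(out, "unit") <- unit
  attr(out, "mean_count") <- mean(rowSums(counts))
  attr(out, "A") <- A
  class(out) <- c("pf_density", "data.frame")
  out
}

#' Hydrocarbon-chain elongation vs lipid radial position
#'
#' For each lipid, each of the two tail chains and each frame, the axial
#' elongation is `|z(last carbon) - z(first carbon)|`; values are binned by
#' the lipid's C2 radial position. Progressive elongation with radius is the
#' quantitative proxy for the gauche-to-all-trans conformational transition
#' of the tails near a hydrophobic pore wall.
#'
#' @param traj A [pf_trajectory()].
#' @param lipids List of lipids; each element a list with `c2` (particle
#'   index of the C2 marker) and `chains` (list of >= 1 integer vectors, the
#'   tail carbons ordered from first to last; each of length >= 2).
#' @param origin Axis origin.
#' @param breaks Radial bin edges; default 0.25 nm over `[0, rho_max]`.
#' @param rho_max Outer radius for the default bins.
#' @param blocks Blocks for the standard error.
#' @return Data frame of class `pf_elongation`: `rho_lo`, `rho_hi`,
#'   `rho_mid`, `chain`, `elongation`, `se`, `n`.
#' @export
chain_elongation <- function(traj, lipids, origin = c(0, 0, 0), breaks = NULL,
                             rho_max = 4, blocks = 5) {
  if (is.null(breaks)) breaks <- seq(0, rho_max, by = 0.25)
  if (is.unsorted(breaks, strictly = TRUE)) stop("'breaks' must be monotone")
  nb <- length(breaks) - 1L
  nf <- n_frames(traj)
  fb <- .frame_blocks(nf, blocks)
  n_chain <- unique(vapply(lipids, function(l) length(l$chains), integer(1)))
  if (length(n_chain) != 1L) stop("all lipids must have the same chain count")
  for (l in lipids) for (ch in l$chains)
    if (length(ch) < 2L) stop("each chain needs at least 2 atoms")

  rows <- list()
  for (ci in seq_len(n_chain)) {
    first <- vapply(lipids, function(l) l$chains[[ci]][1], numeric(1))
    last <- vapply(lipids, function(l) tail(l$chains[[ci]], 1), numeric(1))
    c2 <- vapply(lipids, function(l) l$c2, numeric(1))
    elong <- abs(traj$coords[, last, 3, drop = FALSE] -
                 traj$coords[, first, 3, drop = FALSE])
    dim(elong) <- c(nf, length(lipids))
    ar <- .axial_radial(traj, c2, origin)
    rho <- sqrt(ar$rho2)
    bin <- findInterval(rho, breaks, rightmost.closed = TRUE)
    keep <- bin >= 1L & bin <= nb
    blk <- matrix(fb, nf, length(lipids))
    e <- elong[keep]; b <- bin[keep]; k <- blk[keep]
    mu <- as.numeric(tapply(e, factor(b, levels = seq_len(nb)), mean))
    n <- as.numeric(table(factor(b, levels = seq_len(nb))))
    se <- vapply(seq_len(nb), function(bb)
      .block_se(vapply(seq_len(blocks), function(kk) {
        v <- e[b == bb & k == kk]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))), numeric(1))
    rows[[ci]] <- data.frame(
      rho_lo = breaks[-length(breaks)], rho_hi = breaks[-1],
      rho_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
      chain = ci, elongation = mu, se = se, n = n
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pf_elongation", "data.frame")
  out
}

#' Backbone RMSD time series
#'
#' Cartesian RMSD of a selection against a reference frame, optionally after
#' optimal rigid-body (Kabsch) superposition. Superposition and RMSD are
#' computed with \pkg{bio3d}.
#'
#' @param traj A [pf_trajectory()].
#' @param sel A [selection()] (e.g. role `"protein-backbone"`).
#' @param reference A [pf_frame()] with the same particle count as the
#'   trajectory, or a frame index into `traj`.
#' @param superpose If `TRUE` (default), rotate+translate each frame onto the
#'   reference before the RMSD; if `FALSE`, raw Cartesian RMSD.
#' @return Data frame of class `pf_rmsd` with columns `time` (ns) and `rmsd`
#'   (nm); attribute `superpose` records the mode.
#' @export
backbone_rmsd <- function(traj, sel, reference = 1L, superpose = TRUE) {
  idx <- sel$indices
  if (is.numeric(reference) && length(reference) == 1L) {
    reference <- frame_at(traj, reference)
  }
  if (!inherits(reference, "pf_frame"))
    stop("'reference' must be a pf_frame or a frame index")
  if (nrow(reference$positions) != n_particles(traj))
    stop("reference and trajectory particle counts differ")
  ref <- as.vector(t(reference$positions[idx, , drop = FALSE]))
  nf <- n_frames(traj)
  mat <- matrix(NA_real_, nf, length(idx) * 3L)
  for (k in 1:3) mat[, seq(k, ncol(mat), by = 3L)] <- traj$coords[, idx, k]
  if (superpose)
    mat <- bio3d::fit.xyz(fixed = ref, mobile = mat,
                          fixed.inds = seq_along(ref),
                          mobile.inds = seq_along(ref))
  dev2 <- sweep(mat, 2, ref)^2
  r <- sqrt(rowMeans(dev2[, seq(1, ncol(mat), 3), drop = FALSE] +
                     dev2[, seq(2, ncol(mat), 3), drop = FALSE] +
                     dev2[, seq(3, ncol(mat), 3), drop = FALSE]))
  out <- data.frame(time = traj$times, rmsd = as.numeric(r))
  attr(out, "superpose") <- superpose
  class(out) <- c("pf_rmsd", "data.frame")
  out
}
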