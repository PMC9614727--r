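## Directed water permeation counting.
##
## A crossing event is a full plane-to-plane traversal: a particle last seen
## beyond one entry/exit plane of the channel is next seen beyond the other,
## with every intervening frame strictly between the planes radially inside
## the channel. Midplane fluctuations and vestibule excursions therefore do
## not count; a brief radial excursion beyond the channel radius while
## between the planes voids the event (strict sealing semantics). Particles
## that start between the planes are assigned the side of their first exit
## and complete no event there. Re-crossings cancel in the net count but are
## retained individually.

#' Detect directed channel crossing events
#'
#' Runs an incremental per-particle three-state machine (below / inside /
#' above) over an axis-unwrapped trajectory. Direction +1 is a crossing from
#' below `z_lo` to above `z_hi` (region I to region II), -1 the reverse.
#'
#' @param traj A [pf_trajectory()], unwrapped along the axis (see
#'   [unwrap_axis()]). Apparent axial jumps larger than half the box edge are
#'   refused with a pointer to `unwrap_axis`.
#' @param waters A [selection()] with role `"water-oxygen"`.
#' @param geom A [channel_geometry()]; entry/exit planes must lie inside the
#'   sampled z-range for events to be observable.
#' @return A data frame of class `pf_crossings` with columns `particle`
#'   (index into the full particle set), `direction` (+1/-1), `t_entry`,
#'   `t_exit` (ns). `t_entry` is the first frame at which the traversal is
#'   seen between the planes (or the frame before a single-step jump);
#'   `t_exit` the first frame beyond the far plane. Attribute `duration`
#'   carries the sampled duration.
#' @export
detect_crossings <- function(traj, waters, geom) {
  stopifnot(inherits(traj, "pf_trajectory"), inherits(geom, "pf_channel"))
  if (waters$role != "water-oxygen")
    stop("'waters' must have role 'water-oxygen'")
  ar <- .axial_radial(traj, waters$indices, geom$origin)
  z <- ar$z
  nf <- nrow(z)
  if (nf > 1L) {
    dz <- abs(z[-1, , drop = FALSE] - z[-nf, , drop = FALSE])
    if (any(dz > traj$box[-1, 3] / 2))
      stop("axial jump larger than half the box edge: the trajectory looks ",
           "wrapped; run unwrap_axis() first")
  }
  r2 <- geom$radius^2
  rho2 <- ar$rho2
  np <- ncol(z)
  times <- traj$times

  ## region code per frame: -1 below z_lo, +1 above z_hi, 0 between planes
  region <- function(i) {
    zi <- z[i, ]
    (zi > geom$z_hi) - (zi < geom$z_lo)
  }

  side <- region(1)               # -1/+1 known side; 0 = started inside
  origin <- integer(np)           # transit origin side; 0 = not in transit
  entry <- numeric(np)
  ok <- logical(np)
  ev_p <- integer(0); ev_d <- integer(0); ev_in <- numeric(0); ev_out <- numeric(0)

  for (i in seq_len(nf)[-1]) {
    r <- region(i)
    transit <- origin != 0L

    ins <- r == 0L
    ## radial containment check for frames strictly between the planes
    upd <- ins & transit
    if (any(upd)) ok[upd] <- ok[upd] & (rho2[i, upd] <= r2)
    ## enter transit from a known side
    ent <- ins & !transit & side != 0L
    if (any(ent)) {
      origin[ent] <- side[ent]
      entry[ent] <- times[i]
      ok[ent] <- rho2[i, ent] <= r2
    }

    out <- !ins
    if (any(out)) {
      ## complete a traversal
      done <- out & transit & (r == -origin)
      good <- done & ok
      if (any(good)) {
        ev_p <- c(ev_p, which(good))
        ev_d <- c(ev_d, r[good])
        ev_in <- c(ev_in, entry[good])
        ev_out <- c(ev_out, rep(times[i], sum(good)))
      }
      ## direct plane-to-plane jump with no intervening inside frame
      jump <- out & !transit & side != 0L & (r == -side)
      if (any(jump)) {
        ev_p <- c(ev_p, which(jump))
        ev_d <- c(ev_d, r[jump])
        ev_in <- c(ev_in, rep(times[i - 1L], sum(jump)))
        ev_out <- c(ev_out, rep(times[i], sum(jump)))
      }
      ## all particles now beyond a plane adopt that side, transit ends
      side[out] <- r[out]
      origin[out] <- 0L
    }
  }

  ev <- data.frame(particle = waters$indices[ev_p],
                   direction = as.integer(ev_d),
                   t_entry = ev_in, t_exit = ev_out)
  ev <- ev[order(ev$t_exit, ev$particle), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("pf_crossings", "data.frame")
  attr(ev, "duration") <- duration(traj)
  attr(ev, "geom") <- geom
  ev
}

#' Count membrane crossings outside the channel (sealing check)
#'
#' A sealed membrane lets water through only via the channel. This runs the
#' traversal state machine on the membrane z-interval with no radial
#' requirement and counts completed traversals whose path between the planes
#' was ever radially outside `geom$radius` — i.e. leaks through the lipid
#' annulus or the lipid--wall interface. The sealed-membrane contract is a
#' leak count of exactly 0.
#'
#' @inheritParams detect_crossings
#' @param membrane z-interval `c(lo, hi)` of the membrane slab (nm, relative
#'   to the channel origin); defaults to the channel planes.
#' @return Integer leak count.
#' @export
seal_check <- function(traj, waters, geom, membrane = c(geom$z_lo, geom$z_hi)) {
  stopifnot(inherits(traj, "pf_trajectory"), inherits(geom, "pf_channel"))
  if (length(waters$indices) == 0L) return(0L)
  ar <- .axial_radial(traj, waters$indices, geom$origin)
  z <- ar$z
  rho2 <- ar$rho2
  r2 <- geom$radius^2
  nf <- nrow(z); np <- ncol(z)
  times <- traj$times
  lo <- membrane[1]; hi <- membrane[2]

  side <- (z[1, ] > hi) - (z[1, ] < lo)
  origin <- integer(np)
  outside <- logical(np)   # path ever radially outside the channel
  leaks <- 0L
  for (i in seq_len(nf)[-1]) {
    r <- (z[i, ] > hi) - (z[i, ] < lo)
    transit <- origin != 0L
    ins <- r == 0L
    upd <- ins & transit
    if (any(upd)) outside[upd] <- outside[upd] | (rho2[i, upd] > r2)
    ent <- ins & !transit & side != 0L
    if (any(ent)) {
      origin[ent] <- side[ent]
      outside[ent] <- rho2[i, ent] > r2
    }
    out <- !ins
    if (any(out)) {
      done <- out & transit & (r == -origin)
      leaks <- leaks + sum(done & outside)
      side[out] <- r[out]
      origin[out] <- 0L
    }
  }
  leaks
}

#' Net water flux from crossing events
#'
#' Computes the net molecular flux `J_W = (N_plus - N_minus) / duration` and
#' the volume flux per membrane area `J_v = J_W v_W / A` (Darcy-law form
#' `J_v = L_P dP`). The standard error of `J_W` comes from block averaging:
#' the time span is cut into `blocks` equal blocks, the net rate is computed
#' per block, and the SE of the block mean is reported.
#'
#' @param events A `pf_crossings` data frame from [detect_crossings()] (or
#'   any data frame with `direction` and `t_exit` columns).
#' @param duration Sampled duration, ns (> 0).
#' @param geom A [channel_geometry()] (used for the default area).
#' @param v_W Water molecular volume, nm^3.
#' @param A Membrane area for the flux normalization, nm^2; defaults to the
#'   channel cross-section `pi * radius^2`.
#' @param blocks Number of blocks for the standard error (default 5).
#' @param se_method `"block"` (default): block-averaged SE, robust to the
#'   time correlation of real trajectories. `"counting"`: Poisson counting
#'   error `sqrt(N_plus + N_minus) / duration`, exact when crossing events
#'   are independent (as in the synthetic generator).
#' @param t0 Start of the sampled window (ns; default 0).
#' @return An object of class `pf_flux`: list with `N_plus`, `N_minus`,
#'   `duration`, `J_W` (ns^-1) and its SE, `J_v_nm_ns` (nm/ns), `J_v_se`,
#'   `J_v_cm_s` (cm/s), `A`, `v_W`.
#' @export
net_flux <- function(events, duration, geom = attr(events, "geom"),
                     v_W = pf_constants$v_W, A = NULL, blocks = 5,
                     se_method = c("block", "counting"), t0 = 0) {
  if (!is.finite(duration) || duration <= 0) stop("'duration' must be > 0")
  se_method <- match.arg(se_method)
  if (is.null(A)) {
    if (is.null(geom)) stop("supply 'geom' or 'A'")
    A <- pi * geom$radius^2
  }
  n_plus <- sum(events$direction > 0)
  n_minus <- sum(events$direction < 0)
  J_W <- (n_plus - n_minus) / duration
  if (se_method == "block") {
    ## block-averaged SE of the net rate
    edges <- seq(t0, t0 + duration, length.out = blocks + 1)
    b <- pmin(pmax(findInterval(events$t_exit, edges, rightmost.closed = TRUE),
                   1L), blocks)
    net_b <- vapply(seq_len(blocks), function(k)
      sum(events$direction[b == k]), numeric(1)) / (duration / blocks)
    J_W_se <- stats::sd(net_b) / sqrt(blocks)
  } else {
    J_W_se <- sqrt(n_plus + n_minus) / duration
  }
  J_v <- J_W * v_W / A
  structure(list(N_plus = n_plus, N_minus = n_minus, duration = duration,
                 J_W = J_W, J_W_se = J_W_se,
                 J_v_nm_ns = J_v, J_v_se = J_W_se * v_W / A,
                 J_v_cm_s = J_v * .CM_S_PER_NM_NS,
                 A = A, v_W = v_W, blocks = blocks),
            class = "pf_flux")
}

#' @export
print.pf_flux <- function(x, ...) {
  cat(sprintf(paste0("<pf_flux> N+ = %d, N- = %d over %g ns\n",
                     "  J_W = %g +/- %g ns^-1; J_v = %g nm/ns (%g cm/s), ",
                     "A = %g nm^2\n"),
              x$N_plus, x$N_minus, x$duration, x$J_W, x$J_W_se,
              x$J_v_nm_ns, x$J_v_cm_s, x$A))
  invisible(x)
}
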