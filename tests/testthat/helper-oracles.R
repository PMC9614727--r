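# Independent oracles used across tests.

# Exhaustive per-particle re-scan of the crossing state machine, written as
# plain scalar logic (no vectorized state bookkeeping): one particle at a
# time, one frame at a time.
brute_force_crossings <- function(traj, waters, geom) {
  out <- list()
  times <- traj$times
  for (p in waters$indices) {
    x <- traj$coords[, p, 1] - geom$origin[1]
    y <- traj$coords[, p, 2] - geom$origin[2]
    z <- traj$coords[, p, 3] - geom$origin[3]
    rad_ok <- (x * x + y * y) <= geom$radius^2
    side <- 0L; org <- 0L; ok <- TRUE; ent <- NA_real_
    for (i in seq_along(z)) {
      r <- if (z[i] < geom$z_lo) -1L else if (z[i] > geom$z_hi) 1L else 0L
      if (r == 0L) {
        if (org != 0L) {
          ok <- ok && rad_ok[i]
        } else if (side != 0L) {
          org <- side; ent <- times[i]; ok <- rad_ok[i]
        }
      } else {
        if (org != 0L) {
          if (r == -org && ok)
            out[[length(out) + 1L]] <- data.frame(
              particle = p, direction = r, t_entry = ent, t_exit = times[i])
          org <- 0L
        } else if (side != 0L && r == -side) {
          out[[length(out) + 1L]] <- data.frame(
            particle = p, direction = r, t_entry = times[i - 1L],
            t_exit = times[i])
        }
        side <- r
      }
    }
  }
  if (!length(out))
    return(data.frame(particle = integer(0), direction = integer(0),
                      t_entry = numeric(0), t_exit = numeric(0)))
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$t_exit, ev$particle), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# Trajectory of independent axial random walks (continuous, unwrapped).
# Each particle keeps a lateral home position -- some inside the channel
# radius, some outside -- plus per-frame jitter, so both completed and
# radially voided traversals occur.
random_walk_traj <- function(np, nf, step = 0.6, box = c(6, 6, 30),
                             rho_span = 1.8, jit = 0.15, dt = 0.1) {
  z <- apply(matrix(rnorm(nf * np, 0, step), nf, np), 2, cumsum) +
    matrix(rnorm(np, 0, 3), nf, np, byrow = TRUE)
  x0 <- runif(np, -rho_span, rho_span)
  y0 <- runif(np, -rho_span, rho_span)
  coords <- array(NA_real_, c(nf, np, 3))
  coords[, , 1] <- matrix(x0, nf, np, byrow = TRUE) +
    matrix(rnorm(nf * np, 0, jit), nf, np)
  coords[, , 2] <- matrix(y0, nf, np, byrow = TRUE) +
    matrix(rnorm(nf * np, 0, jit), nf, np)
  coords[, , 3] <- z
  pf_trajectory(coords, times = (seq_len(nf) - 1) * dt, box = box)
}

# Single-particle trajectory from an explicit z path (radially on-axis by
# default), for hand-traced crossing cases.
traj_from_z <- function(zpath, rho = 0, box = c(6, 6, 30), dt = 0.1) {
  nf <- length(zpath)
  coords <- array(0, c(nf, 1, 3))
  coords[, 1, 1] <- rho
  coords[, 1, 3] <- zpath
  pf_trajectory(coords, times = (seq_len(nf) - 1) * dt, box = box)
}

water_sel <- function(n, idx = seq_len(n))
  selection(idx, role = "water-oxygen", n_particles = n)

default_geom <- function() channel_geometry(radius = 1, z_lo = -2, z_hi = 2)

# Multiset comparison of event logs on (particle, direction).
same_events <- function(a, b) {
  key <- function(e) sort(paste(e$particle, e$direction))
  identical(key(a), key(b))
}
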