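## Seeded synthetic systems with analytic ground truth.
##
## The channel generator does not integrate dynamics: crossings are scheduled
## as Poisson events (rejection-free), so the expected net crossing rate is
## exactly g * dP by construction, and every true crossing is recorded in a
## ground-truth log. Scheduled events are rendered as smooth plane-to-plane
## paths radially inside the channel; reservoir waters jitter in bands that
## never touch the entry/exit planes (sealed annulus), unless leak paths are
## requested. Waters outside the channel are represented sparsely to keep
## systems desk-scale.

#' Specification of a synthetic channel-in-membrane system
#'
#' Defaults emulate the study conditions of a single aquaporin channel in a
#' membrane spanning a nanopore: five applied pressures from 10 to 100 MPa; a
#' crossing-rate coefficient `g = 0.0243` events ns^-1 MPa^-1 (equal to
#' L_P / v_W for a channel of hydraulic permeability 7.3e-18 cm^5 N^-1 s^-1);
#' a bilayer whose leaflet separation grows from the biological baseline
#' `h_bio = 2.5` nm with radial distance to the pore wall as
#' `h(rho) = h_bio + delta_h (rho/rho_max)^k`; and water/ion exclusion for
#' `|z| <= z_excl = 1` nm with recovery to bulk density beyond
#' `z_ramp = 4` nm.
#'
#' @param seed Integer RNG seed (one stream per generator call).
#' @param geometry A [channel_geometry()]; default radius 1 nm, planes at
#'   z = -2 and +2 nm (a 4 nm membrane slab).
#' @param box Box edge lengths, nm.
#' @param g Crossing-rate coefficient, events ns^-1 MPa^-1.
#' @param pressures Applied pressure differences, MPa.
#' @param duration Trajectory duration per pressure, ns.
#' @param stride Frame output stride, ns (default 0.02 ns = 20 ps).
#' @param lambda0 Equilibrium (bidirectional) crossing rate, ns^-1; at
#'   dP = 0 forward and backward rates are both `lambda0`, so the expected
#'   net rate is 0 and at pressure dP it is exactly `g * dP`.
#' @param traversal_time Time a scheduled crossing takes to traverse the
#'   channel, ns.
#' @param n_waters Optional total water count; `NULL` sizes the reservoirs
#'   automatically from the scheduled event load.
#' @param n_annulus Sparse waters representing the sealed lipid--wall annulus.
#' @param n_leak Planted leak paths through the annulus (default 0: sealed).
#' @param n_lipids Lipids per leaflet for [gen_lipid_shell()].
#' @param h_bio,delta_h,k Thickness law parameters, nm / nm / exponent.
#' @param rho_max Pore (wall) radius, nm; lipids occupy radii between the
#'   protein edge `rho_min` and `rho_max`.
#' @param rho_min Inner radius of the lipid annulus, nm.
#' @param jitter Gaussian axial (z) jitter of the lipid C2 markers, nm.
#' @param elong_range Axial tail elongation at rho = 0 and rho = rho_max, nm
#'   (linear trans-fraction law in between).
#' @param n_tail Tail carbons per chain.
#' @param z_excl Exclusion half-width around the membrane center, nm.
#' @param z_ramp End of the density recovery ramp, nm.
#' @param bulk_water,bulk_ion Bulk number densities for
#'   [gen_density_system()], nm^-3 (sparse, scaled representation; the ion
#'   fraction ~0.022 matches the ~3.5 wt% salinity of seawater).
#' @return An object of class `pf_synth_spec` (a validated list).
#' @export
synthetic_spec <- function(seed = 1L,
                           geometry = channel_geometry(radius = 1,
                                                       z_lo = -2, z_hi = 2),
                           box = c(10, 10, 24),
                           g = 0.0243,
                           pressures = c(10, 25, 50, 75, 100),
                           duration = 20, stride = 0.02,
                           lambda0 = 0.5, traversal_time = 1,
                           n_waters = NULL, n_annulus = 20, n_leak = 0,
                           n_lipids = 120, h_bio = 2.5, delta_h = 1.5, k = 2,
                           rho_max = 4, rho_min = 1.8, jitter = 0.05,
                           elong_range = c(0.9, 1.9), n_tail = 8,
                           z_excl = 1, z_ramp = 4,
                           bulk_water = 3, bulk_ion = 0.066) {
  stopifnot(inherits(geometry, "pf_channel"))
  if (g < 0 || lambda0 < 0 || duration <= 0 || stride <= 0 ||
      traversal_time <= 0 || any(pressures < 0) || n_leak < 0 ||
      h_bio <= 0 || delta_h < 0 || jitter < 0 || z_excl < 0 ||
      bulk_water < 0 || bulk_ion < 0)
    stop("rates, durations and densities must be nonnegative; h_bio > 0")
  if (rho_max > box[1] / 2 || rho_max > box[2] / 2)
    stop("'rho_max' must fit inside the box")
  structure(list(seed = as.integer(seed), geometry = geometry, box = box,
                 g = g, pressures = pressures, duration = duration,
                 stride = stride, lambda0 = lambda0,
                 traversal_time = traversal_time, n_waters = n_waters,
                 n_annulus = n_annulus, n_leak = n_leak,
                 n_lipids = n_lipids, h_bio = h_bio, delta_h = delta_h, k = k,
                 rho_max = rho_max, rho_min = rho_min, jitter = jitter,
                 elong_range = elong_range, n_tail = n_tail,
                 z_excl = z_excl, z_ramp = z_ramp,
                 bulk_water = bulk_water, bulk_ion = bulk_ion),
            class = "pf_synth_spec")
}

#' Imposed bilayer-thickness law of a synthetic spec
#' @param spec A [synthetic_spec()].
#' @param rho Radial positions, nm.
#' @return `h_bio + delta_h * (rho / rho_max)^k`, nm.
#' @export
thickness_law <- function(spec, rho) {
  spec$h_bio + spec$delta_h * (rho / spec$rho_max)^spec$k
}

#' Generate a synthetic channel trajectory with ground-truth crossings
#'
#' Water crossings through the channel are scheduled as two independent
#' Poisson processes, forward at rate `lambda0 + g * dP` and backward at
#' `lambda0` (for `dP >= 0`), so the expected net rate is exactly `g * dP`.
#' Each scheduled event takes an idle water from the origin-side reservoir
#' and renders a smooth traversal radially inside the channel; the particle
#' then joins the destination reservoir. Reservoir and annulus waters jitter
#' in z-bands that never reach the entry/exit planes, so the membrane is
#' sealed except for `n_leak` planted traversals at a radius outside the
#' channel.
#'
#' @param spec A [synthetic_spec()].
#' @param delta_P Applied pressure difference, MPa.
#' @param seed RNG seed for this call (default `spec$seed`). The same seed
#'   gives a bit-identical trajectory and log.
#' @return A list of class `pf_synth_run`:
#'   \describe{
#'     \item{trajectory}{A [pf_trajectory()] (axially continuous; no
#'       unwrapping needed).}
#'     \item{waters}{A `water-oxygen` [selection()] of all waters.}
#'     \item{geometry}{The channel geometry.}
#'     \item{events}{Ground-truth log: data frame `particle`, `direction`,
#'       `t_start`, `t_end`, `leak`.}
#'     \item{params}{Seed, rates and counts actually used (including any
#'       events dropped for want of an idle particle; 0 under automatic
#'       reservoir sizing).}
#'   }
#' @export
gen_channel_trajectory <- function(spec, delta_P, seed = spec$seed) {
  stopifnot(inherits(spec, "pf_synth_spec"))
  if (delta_P < 0) stop("'delta_P' must be >= 0 (reverse the axis instead)")
  set.seed(seed)
  geom <- spec$geometry
  Tdur <- spec$duration
  lam_f <- spec$lambda0 + spec$g * delta_P
  lam_b <- spec$lambda0
  tau <- spec$traversal_time
  cool <- tau / 2

  ## Poisson event schedule
  n_f <- stats::rpois(1, lam_f * Tdur)
  n_b <- stats::rpois(1, lam_b * Tdur)
  ev <- data.frame(
    t = c(sort(stats::runif(n_f, 0, Tdur - tau)),
          sort(stats::runif(n_b, 0, Tdur - tau))),
    dir = rep(c(1L, -1L), c(n_f, n_b))
  )
  ev <- ev[order(ev$t), , drop = FALSE]

  ## reservoir sizing: net transfer + fluctuation + concurrency margin
  n_side <- if (is.null(spec$n_waters)) {
    ceiling(spec$g * delta_P * Tdur +
              4 * sqrt((lam_f + lam_b) * Tdur + 1) +
              2 * max(lam_f, lam_b) * (tau + cool) + 5)
  } else {
    max(2L, floor((spec$n_waters - spec$n_annulus - spec$n_leak) / 2))
  }
  np <- 2L * n_side + spec$n_annulus + spec$n_leak
  id_below <- seq_len(n_side)
  id_above <- n_side + seq_len(n_side)
  id_ann <- 2L * n_side + seq_len(spec$n_annulus)
  id_leak <- 2L * n_side + spec$n_annulus + seq_len(spec$n_leak)

  times <- seq(0, Tdur, by = spec$stride)
  nf <- length(times)

  ## idle bands: clear of the planes by a margin larger than any jitter
  band_lo <- c(geom$z_lo - 2.0, geom$z_lo - 0.6)
  band_hi <- c(geom$z_hi + 0.6, geom$z_hi + 2.0)
  z_start <- geom$z_lo - 1.0
  z_end <- geom$z_hi + 1.0

  zmat <- matrix(NA_real_, nf, np)
  zmat[, c(id_below, id_ann, id_leak)] <-
    stats::runif(nf * (n_side + spec$n_annulus + spec$n_leak),
                 band_lo[1], band_lo[2])
  zmat[, id_above] <- stats::runif(nf * n_side, band_hi[1], band_hi[2])

  ## radial placement: channel-pool waters stay within 0.9 R at all times,
  ## annulus waters in (R, rho_max], leak waters at a fixed outside radius
  rr <- sqrt(stats::runif(nf * 2 * n_side)) * 0.9 * geom$radius
  th <- stats::runif(nf * 2 * n_side, 0, 2 * pi)
  xmat <- matrix(0, nf, np); ymat <- matrix(0, nf, np)
  xmat[, c(id_below, id_above)] <- rr * cos(th)
  ymat[, c(id_below, id_above)] <- rr * sin(th)
  if (spec$n_annulus > 0) {
    ra <- stats::runif(nf * spec$n_annulus, geom$radius * 1.1, spec$rho_max)
    ta <- stats::runif(nf * spec$n_annulus, 0, 2 * pi)
    xmat[, id_ann] <- ra * cos(ta)
    ymat[, id_ann] <- ra * sin(ta)
  }
  r_leak <- (geom$radius + spec$rho_max) / 2
  if (spec$n_leak > 0) {
    tl <- stats::runif(nf * spec$n_leak, 0, 2 * pi)
    xmat[, id_leak] <- r_leak * cos(tl)
    ymat[, id_leak] <- r_leak * sin(tl)
  }

  ## schedule rendering: pick idle origin-side particles, draw linear paths
  side <- rep(c(-1L, 1L), c(n_side, n_side))   # channel pool only
  busy_until <- rep(-Inf, 2L * n_side)
  log_p <- integer(0); log_d <- integer(0); log_t0 <- numeric(0)
  dropped <- 0L
  pool <- seq_len(2L * n_side)
  for (j in seq_len(nrow(ev))) {
    t0 <- ev$t[j]; d <- ev$dir[j]
    cand <- pool[side == -d & busy_until <= t0]
    if (!length(cand)) { dropped <- dropped + 1L; next }
    p <- cand[1]
    busy_until[p] <- t0 + tau + cool
    side[p] <- d
    w <- times >= t0 & times <= t0 + tau
    frac <- (times[w] - t0) / tau
    if (d > 0) zmat[w, p] <- z_start + frac * (z_end - z_start)
    else       zmat[w, p] <- z_end + frac * (z_start - z_end)
    after <- times > t0 + tau
    zmat[after, p] <- if (d > 0)
      stats::runif(sum(after), band_hi[1], band_hi[2])
    else
      stats::runif(sum(after), band_lo[1], band_lo[2])
    log_p <- c(log_p, p); log_d <- c(log_d, d); log_t0 <- c(log_t0, t0)
  }

  ## planted leak traversals (one per leak particle, upward)
  leak_t0 <- numeric(0)
  if (spec$n_leak > 0) {
    leak_t0 <- sort(stats::runif(spec$n_leak, 0, Tdur - tau))
    for (i in seq_len(spec$n_leak)) {
      p <- id_leak[i]; t0 <- leak_t0[i]
      w <- times >= t0 & times <= t0 + tau
      frac <- (times[w] - t0) / tau
      zmat[w, p] <- z_start + frac * (z_end - z_start)
      after <- times > t0 + tau
      zmat[after, p] <- stats::runif(sum(after), band_hi[1], band_hi[2])
    }
  }

  coords <- array(NA_real_, c(nf, np, 3))
  coords[, , 1] <- xmat + geom$origin[1]
  coords[, , 2] <- ymat + geom$origin[2]
  coords[, , 3] <- zmat + geom$origin[3]
  traj <- pf_trajectory(coords, times, spec$box)

  events <- data.frame(
    particle = c(log_p, id_leak),
    direction = c(log_d, rep(1L, spec$n_leak)),
    t_start = c(log_t0, leak_t0),
    t_end = c(log_t0, leak_t0) + tau,
    leak = rep(c(FALSE, TRUE), c(length(log_p), spec$n_leak))
  )
  events <- events[order(events$t_start), , drop = FALSE]
  rownames(events) <- NULL

  structure(list(
    trajectory = traj,
    waters = selection(seq_len(np), role = "water-oxygen", name = "waters",
                       n_particles = np),
    geometry = geom,
    events = events,
    params = list(seed = seed, delta_P = delta_P, lambda_f = lam_f,
                  lambda_b = lam_b, n_side = n_side, n_particles = np,
                  dropped = dropped, duration = Tdur, stride = spec$stride)
  ), class = "pf_synth_run")
}

#' Generate a synthetic lipid shell with an imposed thickness law
#'
#' Places upper/lower leaflet C2 markers at `z = +/- h(rho)/2` plus Gaussian
#' jitter, with `h(rho) = h_bio + delta_h (rho/rho_max)^k`, and two tail
#' chains per lipid whose axial elongation grows linearly in rho between
#' `elong_range[1]` and `elong_range[2]` (the trans-fraction law). All
#' parameters are stored as ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @param n_frames Number of frames (fresh jitter per frame).
#' @param seed RNG seed (default `spec$seed`).
#' @return A list of class `pf_synth_shell`: `trajectory`, selections
#'   `c2_upper` / `c2_lower`, `lipids` (for [chain_elongation()]), `rho`
#'   (per-lipid radial positions, per leaflet), and `law` (the imposed
#'   thickness and elongation functions).
#' @export
gen_lipid_shell <- function(spec, n_frames = 50, seed = spec$seed) {
  stopifnot(inherits(spec, "pf_synth_spec"))
  set.seed(seed)
  nl <- spec$n_lipids
  nt <- spec$n_tail
  per_lipid <- 1L + 2L * nt            # C2 + two chains
  np <- 2L * nl * per_lipid
  elong_at <- function(rho)
    spec$elong_range[1] +
      (spec$elong_range[2] - spec$elong_range[1]) * rho / spec$rho_max

  rho_u <- stats::runif(nl, spec$rho_min, spec$rho_max)
  rho_l <- stats::runif(nl, spec$rho_min, spec$rho_max)
  th_u <- stats::runif(nl, 0, 2 * pi)
  th_l <- stats::runif(nl, 0, 2 * pi)

  base <- function(rho, th, sgn) {
    h <- thickness_law(spec, rho)
    c2z <- sgn * h / 2
    x0 <- rho * cos(th); y0 <- rho * sin(th)
    el <- elong_at(rho)
    list(x0 = x0, y0 = y0, c2z = c2z, el = el)
  }
  up <- base(rho_u, th_u, +1)
  lo <- base(rho_l, th_l, -1)

  ## particle layout: [upper lipids | lower lipids], each lipid =
  ## C2, chain1 (nt), chain2 (nt). Base positions are exact; the C2 markers
  ## get fresh Gaussian jitter each frame, chain bead z stays exact so the
  ## per-frame elongation equals the imposed law.
  lipids <- vector("list", 2L * nl)
  base <- matrix(NA_real_, np, 3)
  is_c2 <- logical(np)
  build <- function(off, b, sgn, li0) {
    for (i in seq_len(nl)) {
      i0 <- off + (i - 1L) * per_lipid
      c2 <- i0 + 1L
      ch1 <- i0 + 1L + seq_len(nt)
      ch2 <- i0 + 1L + nt + seq_len(nt)
      lipids[[li0 + i]] <<- list(c2 = c2, chains = list(ch1, ch2))
      is_c2[c2] <<- TRUE
      zsteps <- seq(0, b$el[i], length.out = nt)
      base[c2, ] <<- c(b$x0[i], b$y0[i], b$c2z[i])
      for (ch in list(ch1, ch2)) {
        base[ch, 1] <<- b$x0[i]
        base[ch, 2] <<- b$y0[i]
        base[ch, 3] <<- b$c2z[i] - sgn * zsteps
      }
    }
  }
  build(0L, up, +1, 0L)
  build(nl * per_lipid, lo, -1, nl)

  ## jitter perturbs the marker's axial position only, so radial binning is
  ## exact and the imposed thickness law is unbiased per bin
  coords <- array(NA_real_, c(n_frames, np, 3))
  n_c2 <- sum(is_c2)
  for (k in 1:3) {
    coords[, , k] <- matrix(base[, k], n_frames, np, byrow = TRUE)
    if (spec$jitter > 0 && k == 3L)
      coords[, is_c2, k] <- coords[, is_c2, k] +
        stats::rnorm(n_frames * n_c2, 0, spec$jitter)
  }
  traj <- pf_trajectory(coords, times = (seq_len(n_frames) - 1) * spec$stride,
                        box = spec$box)
  c2_up <- selection((seq_len(nl) - 1L) * per_lipid + 1L,
                     role = "lipid-C2", name = "c2_upper", n_particles = np)
  c2_lo <- selection(nl * per_lipid + (seq_len(nl) - 1L) * per_lipid + 1L,
                     role = "lipid-C2", name = "c2_lower", n_particles = np)
  structure(list(trajectory = traj, c2_upper = c2_up, c2_lower = c2_lo,
                 lipids = lipids, rho = list(upper = rho_u, lower = rho_l),
                 law = list(thickness = function(rho) thickness_law(spec, rho),
                            elongation = elong_at),
                 params = list(seed = seed, n_lipids = nl, jitter = spec$jitter)),
            class = "pf_synth_shell")
}

#' Generate a synthetic water/ion system with an exclusion zone
#'
#' Particles are placed per frame by inverse-CDF sampling from the piecewise
#' axial density: zero for `|z| <= z_excl`, a linear ramp for
#' `z_excl < |z| <= z_ramp`, and the bulk plateau beyond `z_ramp` (a sparse,
#' scaled representation of the water/ion distribution around a membrane-
#' sealed channel). Per-frame counts are Poisson around the target.
#'
#' @param spec A [synthetic_spec()].
#' @param n_frames Number of frames.
#' @param z_max Half-height of the sampled column, nm.
#' @param A Cross-sectional area of the column, nm^2.
#' @param saline If `TRUE`, also place ions at `bulk_ion` with the same
#'   exclusion structure.
#' @param seed RNG seed (default `spec$seed`).
#' @return A list of class `pf_synth_density`: `trajectory`, selections
#'   `water` and `ion`, `A`, and `profile` (the ground-truth density
#'   function of z, nm^-3, per species).
#' @export
gen_density_system <- function(spec, n_frames = 20, z_max = 8, A = 100,
                               saline = FALSE, seed = spec$seed) {
  stopifnot(inherits(spec, "pf_synth_spec"))
  if (z_max <= spec$z_ramp) stop("'z_max' must exceed the ramp end")
  set.seed(seed)
  shape <- function(z) {
    az <- abs(z)
    ifelse(az <= spec$z_excl, 0,
           ifelse(az <= spec$z_ramp,
                  (az - spec$z_excl) / (spec$z_ramp - spec$z_excl), 1))
  }
  ## inverse-CDF sampling on [-z_max, z_max] via rejection-free table lookup
  zs <- seq(-z_max, z_max, length.out = 4001)
  cdf <- cumsum(shape(zs)); cdf <- cdf / cdf[length(cdf)]
  sample_z <- function(n) {
    u <- stats::runif(n)
    zs[findInterval(u, cdf) + 1L]
  }
  ## effective weighted length per species -> mean count
  wlen <- 2 * ((spec$z_ramp - spec$z_excl) / 2 + (z_max - spec$z_ramp))
  n_w_mean <- spec$bulk_water * A * wlen
  n_i_mean <- if (saline) spec$bulk_ion * A * wlen else 0

  ## constant particle count across frames (trajectory invariant): use the
  ## Poisson draw of the first frame for capacity, resample positions per frame
  n_w <- stats::rpois(1, n_w_mean)
  n_i <- if (saline) stats::rpois(1, n_i_mean) else 0L
  np <- n_w + n_i
  if (np == 0L) stop("densities too low: no particles to place")
  side <- sqrt(A)
  coords <- array(NA_real_, c(n_frames, np, 3))
  for (f in seq_len(n_frames)) {
    coords[f, , 1] <- stats::runif(np, -side / 2, side / 2)
    coords[f, , 2] <- stats::runif(np, -side / 2, side / 2)
    coords[f, , 3] <- sample_z(np)
  }
  traj <- pf_trajectory(coords, times = (seq_len(n_frames) - 1) * spec$stride,
                        box = c(side, side, 2 * z_max))
  water <- selection(seq_len(n_w), role = "water-oxygen", name = "water",
                     n_particles = np)
  ion <- selection(if (n_i > 0) n_w + seq_len(n_i) else integer(0),
                   role = "ion", name = "ion", n_particles = np)
  structure(list(
    trajectory = traj, water = water, ion = ion, A = A,
    profile = list(
      shape = shape,
      water_bulk = n_w / (A * wlen),
      ion_bulk = if (saline) n_i / (A * wlen) else 0,
      water = function(z) (n_w / (A * wlen)) * shape(z),
      ion = function(z) (if (saline) n_i / (A * wlen) else 0) * shape(z)
    ),
    params = list(seed = seed, n_water = n_w, n_ion = n_i, z_max = z_max)
  ), class = "pf_synth_density")
}
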