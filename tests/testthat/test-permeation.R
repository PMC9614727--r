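# Crossing detection: hand-traced cases, oracle equivalence, symmetry
# properties, sealing, and flux arithmetic.

test_that("hand-traced traversals are counted with the right direction", {
  geom <- default_geom()
  sel <- water_sel(1)

  # monotone pass below -> above: one event, direction +1
  up <- traj_from_z(seq(-5, 5, by = 0.5))
  ev <- detect_crossings(up, sel, geom)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, 1L)
  expect_lte(ev$t_entry, ev$t_exit)

  # oscillation across the entry plane only: no traversal
  osc <- traj_from_z(rep(c(-3, -1), 10))
  expect_equal(nrow(detect_crossings(osc, sel, geom)), 0L)

  # forward then backward: two events, net zero
  fb <- traj_from_z(c(seq(-5, 5, by = 0.5), seq(4.5, -5, by = -0.5)))
  ev2 <- detect_crossings(fb, sel, geom)
  expect_equal(nrow(ev2), 2L)
  expect_equal(sort(ev2$direction), c(-1L, 1L))
  expect_equal(sum(ev2$direction), 0L)
})

test_that("particles starting inside complete no event at their first exit", {
  geom <- default_geom()
  sel <- water_sel(1)
  # starts at z = 0, exits above (no event), then traverses to below (one
  # event, direction -1)
  z <- c(0, 1, 3, 4, 3, 1, 0, -1, -3, -4)
  ev <- detect_crossings(traj_from_z(z), sel, geom)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, -1L)
})

test_that("radial excursions between the planes void the event", {
  geom <- default_geom()
  sel <- water_sel(1)
  z <- seq(-4, 4, by = 0.5)
  rho <- rep(0, length(z))
  rho[z > -1 & z < 1] <- 1.8        # outside radius 1 while between planes
  traj <- traj_from_z(z, rho = rho)
  expect_equal(nrow(detect_crossings(traj, sel, geom)), 0L)
  # the same path is a leak for the sealing check
  expect_equal(seal_check(traj, sel, geom), 1L)
  # staying within the radius keeps the event
  expect_equal(nrow(detect_crossings(traj_from_z(z), sel, geom)), 1L)
})

test_that("single-step plane-to-plane jumps count when sampling is coarse", {
  geom <- default_geom()
  sel <- water_sel(1)
  ev <- detect_crossings(traj_from_z(c(-3, 3, -3), box = c(6, 6, 30)),
                         sel, geom)
  expect_equal(nrow(ev), 2L)
  expect_equal(sum(ev$direction), 0L)
})

test_that("wrapped input is refused with a pointer to unwrap_axis", {
  geom <- default_geom()
  traj <- traj_from_z(c(14, -14), box = c(6, 6, 30))
  expect_error(detect_crossings(traj, water_sel(1), geom), "unwrap_axis")
})

test_that("incremental detector matches the brute-force re-scan", {
  geom <- default_geom()
  for (seed in 1:3) {
    set.seed(100 + seed)
    traj <- random_walk_traj(np = 120, nf = 150)
    sel <- water_sel(120)
    ev <- detect_crossings(traj, sel, geom)
    bf <- brute_force_crossings(traj, sel, geom)
    expect_equal(nrow(ev), nrow(bf))
    expect_equal(ev$particle, bf$particle)
    expect_equal(ev$direction, bf$direction)
    expect_equal(ev$t_entry, bf$t_entry)
    expect_equal(ev$t_exit, bf$t_exit)
  }
})

test_that("reversing the frame order negates the net count exactly", {
  geom <- default_geom()
  for (seed in 1:5) {
    set.seed(200 + seed)
    traj <- random_walk_traj(np = 80, nf = 120)
    sel <- water_sel(80)
    fwd <- detect_crossings(traj, sel, geom)
    rev_traj <- pf_trajectory(traj$coords[rev(seq_len(n_frames(traj))), , ,
                                          drop = FALSE],
                              times = traj$times, box = traj$box)
    bwd <- detect_crossings(rev_traj, sel, geom)
    expect_equal(sum(bwd$direction), -sum(fwd$direction))
  }
})

test_that("net count is invariant to factor-2 subsampling of slow traversals", {
  spec <- synthetic_spec(seed = 31, duration = 10)
  run <- gen_channel_trajectory(spec, delta_P = 60)
  full <- detect_crossings(run$trajectory, run$waters, run$geometry)
  keep <- seq(1, n_frames(run$trajectory), by = 2)
  if (keep[length(keep)] != n_frames(run$trajectory))
    keep <- c(keep, n_frames(run$trajectory))
  sub <- pf_trajectory(run$trajectory$coords[keep, , , drop = FALSE],
                       times = run$trajectory$times[keep],
                       box = run$trajectory$box[keep, ])
  subev <- detect_crossings(sub, run$waters, run$geometry)
  expect_equal(sum(subev$direction), sum(full$direction))
})

test_that("seal_check reports zero on sealed systems and the planted leaks", {
  spec <- synthetic_spec(seed = 32, duration = 10)
  sealed <- gen_channel_trajectory(spec, delta_P = 50)
  expect_equal(seal_check(sealed$trajectory, sealed$waters, sealed$geometry),
               0L)
  leaky_spec <- synthetic_spec(seed = 33, duration = 10, n_leak = 3)
  leaky <- gen_channel_trajectory(leaky_spec, delta_P = 50)
  expect_equal(seal_check(leaky$trajectory, leaky$waters, leaky$geometry), 3L)
  # leaks are not counted as channel crossings
  ev <- detect_crossings(leaky$trajectory, leaky$waters, leaky$geometry)
  expect_true(same_events(ev, leaky$events[!leaky$events$leak, ]))
  # empty selection
  empty <- selection(integer(0), role = "water-oxygen")
  expect_equal(seal_check(sealed$trajectory, empty, sealed$geometry), 0L)
})

test_that("net_flux arithmetic and error handling", {
  # 100 net events in 10 ns through a 4 nm radius channel
  ev <- data.frame(direction = rep(1L, 100), t_exit = seq(0.05, 9.95,
                                                          length.out = 100))
  geom <- channel_geometry(radius = 4, z_lo = -2, z_hi = 2)
  fl <- net_flux(ev, duration = 10, geom = geom, v_W = 0.0301)
  expect_equal(fl$J_W, 10)
  expect_equal(fl$A, pi * 16)
  expect_equal(fl$J_v_nm_ns, 10 * 0.0301 / (pi * 16), tolerance = 1e-12)
  expect_equal(fl$J_v_nm_ns, 5.99e-3, tolerance = 1e-3)
  expect_equal(fl$J_v_cm_s, fl$J_v_nm_ns * 100)

  none <- data.frame(direction = integer(0), t_exit = numeric(0))
  fl0 <- net_flux(none, duration = 5, geom = geom)
  expect_equal(fl0$J_W, 0)
  expect_equal(fl0$J_v_nm_ns, 0)
  expect_error(net_flux(ev, duration = 0, geom = geom), "'duration' must be > 0")
  expect_error(net_flux(ev, duration = -1, geom = geom), "'duration' must be > 0")
})

test_that("net_flux recovers a Poisson event rate within its standard error", {
  geom <- default_geom()
  lam <- 5; Tdur <- 40
  hits <- vapply(1:50, function(s) {
    set.seed(300 + s)
    n <- rpois(1, lam * Tdur)
    ev <- data.frame(direction = rep(1L, n), t_exit = sort(runif(n, 0, Tdur)))
    fl <- net_flux(ev, duration = Tdur, geom = geom)
    abs(fl$J_W - lam) <= 3 * fl$J_W_se
  }, logical(1))
  expect_gte(sum(hits), 45)
})
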