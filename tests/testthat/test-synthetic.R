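# Synthetic generators: determinism, analytic ground truth, and the
# statistical structure the analyses assume.

test_that("the same seed reproduces trajectories and logs bit for bit", {
  spec <- synthetic_spec(seed = 61, duration = 5)
  a <- gen_channel_trajectory(spec, delta_P = 50)
  b <- gen_channel_trajectory(spec, delta_P = 50)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$events, b$events)
  c <- gen_channel_trajectory(spec, delta_P = 50, seed = 62)
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))

  s1 <- gen_lipid_shell(spec, n_frames = 3)
  s2 <- gen_lipid_shell(spec, n_frames = 3)
  expect_identical(s1$trajectory$coords, s2$trajectory$coords)

  d1 <- gen_density_system(spec, n_frames = 3)
  d2 <- gen_density_system(spec, n_frames = 3)
  expect_identical(d1$trajectory$coords, d2$trajectory$coords)
})

test_that("at zero pressure difference the net crossing count is unbiased", {
  net <- 0; tot <- 0
  for (s in 1:20) {
    spec <- synthetic_spec(seed = 700 + s, duration = 10)
    run <- gen_channel_trajectory(spec, delta_P = 0)
    ev <- run$events[!run$events$leak, ]
    net <- net + sum(ev$direction)
    tot <- tot + nrow(ev)
  }
  expect_lte(abs(net), 3 * sqrt(tot))
})

test_that("the pipeline count equals the generator's ground-truth log exactly", {
  for (s in 1:2) {
    for (dp in c(10, 100)) {
      spec <- synthetic_spec(seed = 800 + s, duration = 10)
      run <- gen_channel_trajectory(spec, delta_P = dp)
      ev <- detect_crossings(run$trajectory, run$waters, run$geometry)
      gt <- run$events[!run$events$leak, ]
      expect_true(same_events(ev, gt))
      expect_equal(sum(ev$direction), sum(gt$direction))
      expect_equal(run$params$dropped, 0L)
    }
  }
})

test_that("scheduled crossings realize the expected net rate g * dP", {
  # aggregate over seeds: mean net count ~ g * dP * T with Poisson noise
  g <- 0.0243; dp <- 75; Tdur <- 20
  net <- 0; var_acc <- 0
  for (s in 1:15) {
    spec <- synthetic_spec(seed = 900 + s)
    run <- gen_channel_trajectory(spec, delta_P = dp)
    ev <- run$events[!run$events$leak, ]
    net <- net + sum(ev$direction)
    var_acc <- var_acc + (spec$lambda0 * 2 + g * dp) * Tdur
  }
  expect_lt(abs(net - 15 * g * dp * Tdur), 4 * sqrt(var_acc))
})

test_that("lipid shell: flat and jitter-free limits are exact", {
  flat <- gen_lipid_shell(synthetic_spec(seed = 63, delta_h = 0, jitter = 0),
                          n_frames = 2)
  z <- flat$trajectory$coords[1, flat$c2_upper$indices, 3]
  expect_equal(z, rep(1.25, length(z)), tolerance = 1e-12)

  exact <- gen_lipid_shell(synthetic_spec(seed = 64, jitter = 0), n_frames = 2)
  rho <- exact$rho$upper
  zc2 <- exact$trajectory$coords[1, exact$c2_upper$indices, 3]
  expect_equal(zc2, exact$law$thickness(rho) / 2, tolerance = 1e-12)
})

test_that("density system: exclusion zone, ramp and bulk plateau", {
  spec <- synthetic_spec(seed = 65)
  sys <- gen_density_system(spec, n_frames = 20, saline = TRUE)
  breaks <- seq(-8, 8, 0.5)
  pw <- axial_density(sys$trajectory, sys$water, breaks = breaks, A = sys$A)
  # construction oracle: zero density in the excluded zone
  core <- pw$z_lo >= -1 & pw$z_hi <= 1
  expect_true(all(pw$density[core] == 0))
  # bulk plateau within counting noise of the stored ground truth
  bulk <- pw$z_lo >= 4.5 | pw$z_hi <= -4.5
  target <- sys$profile$water_bulk
  count_noise <- sqrt(target * sys$A * 0.5 * 20) / (sys$A * 0.5 * 20)
  expect_true(all(abs(pw$density[bulk] - target) < 5 * count_noise))

  # ions share the exclusion structure at their own bulk fraction
  pi_ <- axial_density(sys$trajectory, sys$ion, breaks = breaks, A = sys$A)
  expect_true(all(pi_$density[core] == 0))
  expect_gt(sys$profile$ion_bulk, 0)
  ion_bulk_obs <- mean(pi_$density[bulk])
  expect_lt(abs(ion_bulk_obs - sys$profile$ion_bulk),
            5 * sqrt(sys$profile$ion_bulk * sys$A * 0.5 * 20 *
                       sum(bulk)) / (sys$A * 0.5 * 20 * sum(bulk)))
  # ion-to-water bulk ratio reflects the seawater-like fraction
  expect_equal(sys$profile$ion_bulk / sys$profile$water_bulk, 0.022,
               tolerance = 0.35)
})

test_that("synthetic_spec validates its parameters", {
  expect_error(synthetic_spec(duration = -1), "nonnegative")
  expect_error(synthetic_spec(g = -0.1), "nonnegative")
  expect_error(synthetic_spec(rho_max = 20), "fit inside the box")
  expect_error(gen_channel_trajectory(synthetic_spec(), delta_P = -5),
               ">= 0")
})
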