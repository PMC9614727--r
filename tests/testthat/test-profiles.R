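# Structural profiles: thickness, axial density, chain elongation, RMSD.

test_that("a flat bilayer yields the biological thickness in every occupied bin", {
  spec <- synthetic_spec(seed = 51, delta_h = 0, jitter = 0)
  shell <- gen_lipid_shell(spec, n_frames = 5)
  prof <- radial_thickness(shell$trajectory, shell$c2_upper, shell$c2_lower,
                           rho_max = spec$rho_max)
  occ <- prof[prof$occupied, ]
  expect_gt(nrow(occ), 3)
  expect_equal(occ$thickness, rep(2.5, nrow(occ)), tolerance = 1e-12)
})

test_that("a single lipid per leaflet recovers its exact axial position", {
  coords <- array(0, c(3, 2, 3))
  coords[, 1, 1] <- 1.3; coords[, 1, 3] <- 1.42    # upper: rho 1.3, z 1.42
  coords[, 2, 2] <- 2.6; coords[, 2, 3] <- -1.08   # lower: rho 2.6, z -1.08
  traj <- pf_trajectory(coords, times = 0:2, box = c(10, 10, 10))
  up <- selection(1, role = "lipid-C2", n_particles = 2)
  lo <- selection(2, role = "lipid-C2", n_particles = 2)
  prof <- radial_thickness(traj, up, lo, rho_max = 4)
  b_up <- which(prof$rho_lo <= 1.3 & prof$rho_hi > 1.3)
  b_lo <- which(prof$rho_lo <= 2.6 & prof$rho_hi > 2.6)
  expect_equal(prof$z_upper[b_up], 1.42)
  expect_equal(prof$z_lower[b_lo], -1.08)
  expect_false(prof$occupied[b_up])   # leaflets in different bins
  expect_error(radial_thickness(traj, selection(integer(0), "lipid-C2"), lo),
               "nonempty")
})

test_that("an imposed quadratic thickness law is recovered within calibrated uncertainty", {
  spec <- synthetic_spec(seed = 52)   # h = 2.5 + 1.5 (rho/4)^2, jitter 0.05
  shell <- gen_lipid_shell(spec, n_frames = 50)
  # generator jitter is independent across frames, so the iid SE is the
  # correctly calibrated uncertainty here
  prof <- radial_thickness(shell$trajectory, shell$c2_upper, shell$c2_lower,
                           rho_max = spec$rho_max, se_method = "iid")
  law <- shell$law$thickness
  # expected per-bin thickness from the actual radial draws of each leaflet;
  # per-bin z-scores are checked as a calibrated ensemble (chi-square across
  # bins, hard cap per bin) rather than a simultaneous 2-SE bound, which
  # would be miscalibrated across ~16 bins
  cutb <- function(r) cut(r, seq(0, 4, 0.25), labels = FALSE)
  z <- c()
  for (b in which(prof$occupied & prof$n_upper > 20 & prof$n_lower > 20)) {
    exp_up <- mean(law(shell$rho$upper[cutb(shell$rho$upper) == b])) / 2
    exp_lo <- mean(law(shell$rho$lower[cutb(shell$rho$lower) == b])) / 2
    z <- c(z, (prof$thickness[b] - (exp_up + exp_lo)) / prof$se[b])
  }
  expect_gte(length(z), 8)
  expect_lt(max(abs(z)), 3.5)
  expect_lt(sum(z^2), qchisq(0.999, df = length(z)))
})

test_that("thickness is invariant under rigid axial translation with recentring", {
  spec <- synthetic_spec(seed = 53)
  shell <- gen_lipid_shell(spec, n_frames = 10)
  traj <- shell$trajectory
  np <- n_particles(traj)
  # append a 4-atom 'backbone' centred at the origin
  nf <- n_frames(traj)
  bb <- array(0, c(nf, 4, 3))
  bb[, 1, 1] <- 0.5; bb[, 2, 1] <- -0.5; bb[, 3, 2] <- 0.5; bb[, 4, 2] <- -0.5
  coords <- array(NA_real_, c(nf, np + 4, 3))
  coords[, seq_len(np), ] <- traj$coords
  coords[, np + 1:4, ] <- bb
  base <- pf_trajectory(coords, traj$times, traj$box)
  shifted <- base
  shifted$coords[, , 3] <- shifted$coords[, , 3] + 2.37
  backbone <- selection(np + 1:4, role = "protein-backbone",
                        n_particles = np + 4)
  p0 <- radial_thickness(base, shell$c2_upper, shell$c2_lower,
                         center = backbone)
  p1 <- radial_thickness(shifted, shell$c2_upper, shell$c2_lower,
                         center = backbone)
  expect_equal(p1$thickness, p0$thickness, tolerance = 1e-10)
  expect_equal(p1$z_upper, p0$z_upper, tolerance = 1e-10)
})

test_that("axial density reproduces a uniform gas and conserves counts", {
  set.seed(54)
  N <- 4000; box <- c(5, 5, 10)
  nf <- 10
  coords <- array(runif(nf * N * 3), c(nf, N, 3))
  coords[, , 1] <- coords[, , 1] * 5
  coords[, , 2] <- coords[, , 2] * 5
  coords[, , 3] <- coords[, , 3] * 10 - 5
  traj <- pf_trajectory(coords, times = seq_len(nf) - 1, box = box)
  sel <- water_sel(N)
  prof <- axial_density(traj, sel, breaks = seq(-5, 5, 0.5), A = 25)
  rho_true <- N / prod(box)
  # every bin within counting noise (Poisson-ish, ~sqrt(count)/V_bin/sqrt(nf))
  noise <- sqrt(rho_true * 25 * 0.5 * nf) / (25 * 0.5 * nf)
  expect_true(all(abs(prof$density - rho_true) < 5 * noise))
  # exact conservation: sum(density * bin volume) = mean count per frame
  expect_equal(sum(prof$density * 25 * 0.5), N, tolerance = 1e-12)
  expect_equal(attr(prof, "mean_count"), N)
  # empty selection gives an all-zero profile
  p0 <- axial_density(traj, selection(integer(0), "ion"), A = 25,
                      breaks = seq(-5, 5, 0.5))
  expect_true(all(p0$density == 0))
  expect_error(axial_density(traj, sel, breaks = c(0, 0, 1), A = 25),
               "monotone")
  expect_error(axial_density(traj, sel, breaks = seq(-5, 5, 0.5), A = 0),
               "'A' must be > 0")
})

test_that("mass weighting converts number density to g/cm^3", {
  # bulk water: 33.37 molecules/nm^3 * 18.015 g/mol ~ 0.998 g/cm^3
  nf <- 2; N <- 33370
  set.seed(55)
  coords <- array(runif(nf * N * 3, 0, 10), c(nf, N, 3))
  traj <- pf_trajectory(coords, times = 0:1, box = c(10, 10, 10))
  prof <- axial_density(traj, water_sel(N), breaks = seq(0, 10, 1), A = 100,
                        mass = 18.015)
  expect_equal(mean(prof$density), 0.998, tolerance = 0.01)
  expect_equal(attr(prof, "unit"), "g cm^-3")
})

test_that("chain elongation handles the extended and flat limits exactly", {
  # one lipid: C2 at (1, 0, 1), chain1 straight down 1.5 nm, chain2 in-plane
  coords <- array(0, c(2, 7, 3))
  coords[, 1, ] <- matrix(c(1, 0, 1), 2, 3, byrow = TRUE)
  for (j in 0:2) coords[, 2 + j, ] <- matrix(c(1, 0, 1 - 0.75 * j), 2, 3,
                                             byrow = TRUE)
  for (j in 0:2) coords[, 5 + j, ] <- matrix(c(1 + 0.3 * j, 0, 1), 2, 3,
                                             byrow = TRUE)
  traj <- pf_trajectory(coords, times = 0:1, box = c(10, 10, 10))
  lipids <- list(list(c2 = 1, chains = list(2:4, 5:7)))
  prof <- chain_elongation(traj, lipids, rho_max = 4)
  b <- which(prof$rho_lo <= 1 & prof$rho_hi > 1)
  expect_equal(prof$elongation[prof$chain == 1][b[1]], 1.5)
  expect_equal(prof$elongation[prof$chain == 2][b[1]], 0)
  expect_error(chain_elongation(traj, list(list(c2 = 1, chains = list(2L, 5:7)))),
               "at least 2 atoms")
})

test_that("shell elongation matches direct recomputation and increases with rho", {
  spec <- synthetic_spec(seed = 56)
  shell <- gen_lipid_shell(spec, n_frames = 10)
  prof <- chain_elongation(shell$trajectory, shell$lipids,
                           rho_max = spec$rho_max)
  # brute-force recomputation from stored coordinates
  traj <- shell$trajectory
  for (ci in 1:2) {
    vals <- list()
    for (li in seq_along(shell$lipids)) {
      lp <- shell$lipids[[li]]
      ch <- lp$chains[[ci]]
      e <- abs(traj$coords[, ch[length(ch)], 3] - traj$coords[, ch[1], 3])
      rho <- sqrt(traj$coords[, lp$c2, 1]^2 + traj$coords[, lp$c2, 2]^2)
      vals[[li]] <- data.frame(e = e, bin = findInterval(rho, seq(0, 4, 0.25),
                                                         rightmost.closed = TRUE))
    }
    v <- do.call(rbind, vals)
    sub <- prof[prof$chain == ci, ]
    for (b in which(sub$n > 0)) {
      expect_equal(sub$elongation[b], mean(v$e[v$bin == b]), tolerance = 1e-12)
    }
    # monotone nondecreasing across occupied bins (linear trans-fraction law)
    occ <- sub[sub$n > 20, ]
    expect_true(all(diff(occ$elongation) > -1e-6))
  }
})

test_that("backbone RMSD is zero for identity and rigid motions, exact otherwise", {
  set.seed(57)
  n <- 8
  ref_pos <- matrix(rnorm(n * 3), n, 3)
  sel <- selection(seq_len(n), role = "protein-backbone", n_particles = n)
  ref <- pf_frame(ref_pos + 5, box = c(10, 10, 10))

  # frame identical to reference
  coords <- array(NA_real_, c(3, n, 3))
  coords[1, , ] <- ref_pos + 5
  # rigid rotation + translation
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  coords[2, , ] <- (ref_pos + 5) %*% Rz + matrix(c(1, -2, 0.5), n, 3,
                                                 byrow = TRUE)
  # one atom displaced by 0.4 nm
  disp <- ref_pos + 5
  disp[3, 1] <- disp[3, 1] + 0.4
  coords[3, , ] <- disp
  traj <- pf_trajectory(coords, times = 0:2, box = c(20, 20, 20))

  raw <- backbone_rmsd(traj, sel, reference = ref, superpose = FALSE)
  fit <- backbone_rmsd(traj, sel, reference = ref, superpose = TRUE)
  expect_equal(raw$rmsd[1], 0, tolerance = 1e-12)
  expect_lt(fit$rmsd[2], 1e-10)
  expect_equal(raw$rmsd[3], 0.4 / sqrt(8), tolerance = 1e-10)
  # superposed RMSD never exceeds raw RMSD
  expect_true(all(fit$rmsd <= raw$rmsd + 1e-12))

  bad <- pf_frame(matrix(0, n + 1, 3), box = c(10, 10, 10))
  expect_error(backbone_rmsd(traj, sel, reference = bad), "particle count")
})
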