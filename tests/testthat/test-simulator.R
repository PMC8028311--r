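test_that("random initialization respects counts, bonds and separations", {
  sq <- seq_ref()
  p <- forcefield_params()
  cfg <- sim_config(n_chains = 20, box = 300, seed = 1)
  fr <- initialize_random(sq, cfg, p)
  expect_equal(nrow(fr$positions), 20 * 40)
  # all bonds at r0
  for (c in 1:3) {
    idx <- which(fr$chain_index == c)
    bl <- sqrt(rowSums(diff(fr$positions[idx, ])^2))
    expect_equal(bl, rep(p$r0_bond, 39), tolerance = 1e-9)
  }
  # no nonbonded pair below 3 A (minimum image)
  d <- as.matrix(stats::dist(fr$positions))
  same_chain <- outer(fr$chain_index, fr$chain_index, "==")
  adj <- abs(outer(seq_len(800), seq_len(800), "-")) <= 1
  excl <- same_chain & adj
  diag(excl) <- TRUE
  expect_gte(min(d[!excl]), 3)
  # determinism
  fr2 <- initialize_random(sq, cfg, p)
  expect_identical(fr$positions, fr2$positions)
})

test_that("single-chain initialization is one walk with all bonds at r0", {
  sq <- seq_ref()
  p <- forcefield_params()
  cfg <- sim_config(n_chains = 1, box = 100, seed = 2)
  fr <- initialize_random(sq, cfg, p)
  bl <- sqrt(rowSums(diff(fr$positions)^2))
  expect_equal(bl, rep(p$r0_bond, 39), tolerance = 1e-9)
})

test_that("droplet initialization packs chains inside the requested sphere", {
  sq <- seq_phi(0.2)
  p <- forcefield_params()
  cfg <- sim_config(n_chains = 8, box = 300, seed = 3, init_mode = "droplet")
  fr <- initialize_droplet(sq, cfg, p, droplet_radius = 60)
  centre <- rep(150, 3)
  r <- sqrt(rowSums(sweep(fr$positions, 2, centre)^2))
  expect_true(all(r <= 60 + 1e-9))
  fr2 <- initialize_droplet(sq, cfg, p, droplet_radius = 60)
  expect_identical(fr$positions, fr2$positions)
})

test_that("a droplet as large as the box reproduces a homogeneous density profile", {
  sq <- seq_phi(0.2)
  p <- forcefield_params()
  box <- 120
  cfg <- sim_config(n_chains = 12, box = box, seed = 4, init_mode = "droplet")
  fr <- initialize_droplet(sq, cfg, p, droplet_radius = box / 2)
  cfg_r <- sim_config(n_chains = 12, box = box, seed = 4)
  fr_r <- initialize_random(sq, cfg_r, p)
  # compare radial histograms about the box centre on the inscribed ball
  rad <- function(f) {
    r <- sqrt(rowSums(sweep(f$positions %% box, 2, rep(box / 2, 3))^2))
    graphics::hist(r[r < box / 2], breaks = seq(0, box / 2, length.out = 6),
                   plot = FALSE)$density
  }
  expect_equal(rad(fr), rad(fr_r), tolerance = 0.5)
})

test_that("runs are reproducible and carry increasing time stamps", {
  traj <- short_droplet_run(n_chains = 4, n_steps = 600, save_every = 100)
  traj2 <- short_droplet_run(n_chains = 4, n_steps = 600, save_every = 100)
  expect_identical(traj$positions, traj2$positions)
  expect_true(all(diff(traj$times) > 0))
  expect_equal(n_frames(traj), 6)
})

test_that("free-particle diffusion matches kBT/(m gamma)", {
  # 50 non-interacting beads (hydrophobic with eps_lj = 0)
  p0 <- forcefield_params(eps_lj = 0)
  sqH <- cg_sequence("H")
  cfg <- sim_config(n_chains = 50, n_steps = 40000, save_every = 20,
                    seed = 2, temperature = 300, box = 0, dt = 0.3,
                    gamma = 0.05)
  fr <- cg_frame(matrix(stats::runif(150, 0, 500), 50, 3), 0, 1:50)
  traj <- run_langevin(fr, sqH, cfg, p0)
  D <- diffusion_coefficient(msd_chains(traj))$D
  D_expected <- 0.0019872 * 300 / (cfg$mass * cfg$gamma)
  expect_equal(D, D_expected, tolerance = 0.10)
})

test_that("harmonic dimer samples the Boltzmann bond-length distribution", {
  p <- forcefield_params(cutoff_lj = 7)   # keep nonbonded out of the way
  sq2 <- cg_sequence("++")                # bonded pair; 1-2 excluded anyway
  cfg <- sim_config(n_chains = 1, n_steps = 60000, save_every = 10,
                    seed = 6, temperature = 300, box = 0, dt = 0.2,
                    gamma = 0.5)
  fr <- cg_frame(rbind(c(0, 0, 0), c(3.8, 0, 0)), 0, c(1, 1))
  traj <- run_langevin(fr, sq2, cfg, p)
  r_samp <- apply(traj$positions, 3, function(m) {
    sqrt(sum((m[2, ] - m[1, ])^2))
  })
  r_samp <- r_samp[-(1:500)]
  # Boltzmann density p(r) ~ r^2 exp(-k (r-r0)^2 / kBT), numeric CDF
  kBT <- 0.0019872 * 300
  rg <- seq(2.5, 5.1, length.out = 2000)
  dens <- rg^2 * exp(-p$k_bond * (rg - p$r0_bond)^2 / kBT)
  cdf <- cumsum(dens) / sum(dens)
  ks <- suppressWarnings(stats::ks.test(
    r_samp[seq(1, length(r_samp), by = 20)],  # thin to near-independence
    function(q) stats::approx(rg, cdf, xout = q, yleft = 0, yright = 1)$y))
  expect_gt(ks$p.value, 0.01)
})

test_that("with the thermostat off, descent-started energy never increases at T ~ 0", {
  sq <- seq_phi(0.4)
  p <- forcefield_params(shift_at_cutoff = TRUE)
  # 1 K: thermal noise ~ 1e-3 kcal/mol, far below every barrier; lower
  # temperatures turn the screened-ion potential into a hard wall
  cfg <- sim_config(n_chains = 3, n_steps = 2000, save_every = 100, seed = 8,
                    temperature = 1, box = 100, dt = 0.05, gamma = 0.2)
  fr <- minimize_frame(initialize_random(sq, cfg, p), sq, p)
  traj <- run_langevin(fr, sq, cfg, p)
  etot <- rowSums(traj$energy_log) +
    1.5 * nrow(fr$positions) * 0.0019872 * traj$kinetic_T
  expect_true(all(diff(etot) <= 1e-6 * abs(etot[-length(etot)])))
})

test_that("microcanonical run conserves energy with shifted cutoffs", {
  sq <- seq_ref()
  p <- forcefield_params(shift_at_cutoff = TRUE)
  cfg <- sim_config(n_chains = 3, n_steps = 10000, save_every = 100,
                    seed = 4, temperature = 200, box = 100, dt = 0.02,
                    gamma = 0)
  fr <- minimize_frame(initialize_random(sq, cfg, p), sq, p)
  traj <- run_langevin(fr, sq, cfg, p)
  etot <- rowSums(traj$energy_log) +
    1.5 * nrow(fr$positions) * 0.0019872 * traj$kinetic_T
  expect_lt((max(etot) - min(etot)) / abs(mean(etot)), 1e-4)
})

test_that("long-run kinetic temperature tracks the target within 3%", {
  sq <- seq_ref()
  p <- forcefield_params()
  cfg <- sim_config(n_chains = 10, n_steps = 20000, save_every = 100,
                    seed = 3, temperature = 300, box = 200, dt = 0.3)
  fr <- minimize_frame(initialize_random(sq, cfg, p), sq, p)
  traj <- run_langevin(fr, sq, cfg, p)
  kin <- traj$kinetic_T[-(1:50)]
  expect_equal(mean(kin), 300, tolerance = 0.03)
})

test_that("XYZ round-trip preserves coordinates, box and chain ids", {
  traj <- short_droplet_run(n_chains = 3, n_steps = 400, save_every = 200)
  tf <- tempfile(fileext = ".xyz")
  write_xyz(traj, tf)
  back <- read_xyz(tf)
  expect_equal(back$positions, traj$positions, tolerance = 1e-5)
  expect_equal(back$box, traj$box)
  expect_identical(back$chain_index, traj$chain_index)
  expect_equal(back$times, traj$times, tolerance = 1e-5)
})
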