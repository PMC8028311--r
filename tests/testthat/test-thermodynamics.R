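test_that("Tc fit recovers noise-free scaling-law parameters exactly", {
  pts <- gen_coexistence_curve(Tc_true = 400, A = 1, beta = 0.325,
                               n_points = 5, noise_sd = 0, seed = 1)
  fit <- fit_critical_temperature(pts)
  expect_equal(fit$Tc, 400, tolerance = 1e-6)
  expect_equal(fit$A, 1, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-8)
})

test_that("Tc fit is scale-equivariant in the densities", {
  pts <- gen_coexistence_curve(350, 0.8, n_points = 7, noise_sd = 0.004,
                               seed = 3)
  f1 <- fit_critical_temperature(pts)
  pts2 <- pts
  pts2$rho_dense <- pts2$rho_dense * 7
  pts2$rho_dilute <- pts2$rho_dilute * 7
  f2 <- fit_critical_temperature(pts2)
  expect_equal(f2$Tc, f1$Tc, tolerance = 1e-9)
  expect_equal(f2$A, 7 * f1$A, tolerance = 1e-9)
})

test_that("a coexistence point with vanishing order parameter pins Tc near it", {
  pts <- gen_coexistence_curve(300, 1, n_points = 6, noise_sd = 0, seed = 2)
  tstar <- 0.97 * 300
  pts <- rbind(pts, data.frame(temperature = tstar, rho_dense = 0.5,
                               rho_dilute = 0.5))
  fit <- fit_critical_temperature(pts)
  expect_lte(fit$Tc, tstar + 0.05 * 300)
})

test_that("the generating exponent fits better than a mis-set one", {
  pts <- gen_coexistence_curve(380, 1.2, beta = 0.325, n_points = 8,
                               noise_sd = 0, seed = 4)
  r_true <- fit_critical_temperature(pts, beta = 0.325)$residual_norm
  r_wrong <- fit_critical_temperature(pts, beta = 0.5)$residual_norm
  expect_lt(r_true, r_wrong)
})

test_that("degenerate inputs are refused", {
  flat <- data.frame(temperature = c(200, 250, 300),
                     rho_dense = 0.4, rho_dilute = 0.4)
  expect_error(fit_critical_temperature(flat))
  expect_error(fit_critical_temperature(flat[1:2, ]))
})

test_that("noisy Tc recovery stays within 2% in the median over seeds", {
  errs <- vapply(1:40, function(s) {
    pts <- gen_coexistence_curve(Tc_true = 400, A = 1, n_points = 8,
                                 noise_sd = 0.02, seed = s)
    abs(fit_critical_temperature(pts)$Tc - 400) / 400
  }, numeric(1))
  expect_lt(stats::median(errs), 0.02)
})

test_that("re-entrance detector flags planted re-entrant curves only", {
  normal <- gen_coexistence_curve(350, 1, n_points = 9, noise_sd = 0, seed = 5)
  expect_false(detect_reentrance(normal))
  reent <- gen_coexistence_curve(350, 1, n_points = 9, noise_sd = 0, seed = 5,
                                 reentrant = TRUE)
  expect_true(detect_reentrance(reent))
})

test_that("phase diagram built from synthetic droplet frames recovers Tc within 1%", {
  # frames generated with gen_droplet_config at densities that follow the
  # scaling law; the full pipeline (clustering -> densities -> fit) must
  # invert it
  # single-bead chains sampled uniformly plant the densities sharply; the
  # bead count is held constant across temperatures so the finite-sample
  # convex-hull bias is a common factor, absorbed into the fitted amplitude
  Tc_true <- 500; A <- 0.004; box <- 260
  temps <- Tc_true * seq(0.55, 0.9, length.out = 5)
  n_dense <- 800; n_gas <- 30
  trajs <- list()
  for (i in seq_along(temps)) {
    drho <- A * (1 - temps[i] / Tc_true)^0.325
    rho_dil <- n_gas / box^3
    radius <- (3 * n_dense / (4 * pi * (drho + rho_dil)))^(1 / 3)
    frames <- lapply(1:3, function(k) {
      gen_droplet_config(n_dense, n_gas, 1, rep(radius, 3), box,
                         seed = 100 * i + k)
    })
    trajs[[as.character(temps[i])]] <-
      trajectory_from_frames(frames, times = 1:3)
  }
  pd <- build_phase_diagram(trajs, equil_frac = 0, n_blocks = 3,
                            min_residues = 1)
  expect_false(is.null(pd$fit))
  expect_equal(pd$fit$Tc, Tc_true, tolerance = 0.01)
})

test_that("frozen identical frames at every T refuse the fit", {
  fr <- gen_droplet_config(20, 2, 10, c(45, 45, 45), 250, seed = 9)
  trajs <- list()
  for (tt in c(200, 250, 300)) {
    trajs[[as.character(tt)]] <-
      trajectory_from_frames(list(fr, fr, fr), times = 1:3)
  }
  expect_warning(pd <- build_phase_diagram(trajs, equil_frac = 0), "fit failed")
  expect_null(pd$fit)
})

test_that("interchain energies: hand-built contacts and exact bookkeeping", {
  p <- forcefield_params()
  # phi = 0 chains: inter-chain LJ identically zero
  traj0 <- short_droplet_run(phi = 0, temperature = 220, n_chains = 6,
                             n_steps = 1500, save_every = 300)
  prof0 <- interchain_energy_profile(traj0, p)
  expect_true(all(prof0$E_short == 0))
  expect_equal(prof0$E_total, prof0$E_short + prof0$E_long, tolerance = 1e-12)
  # two parallel 6-bead hydrophobic chains 7 A apart: E_short equals the
  # pen-and-paper sum of analytic 12-10 terms over all inter-chain pairs
  a <- cbind(3.8 * (1:6), 0, 0) + 100
  b <- cbind(3.8 * (1:6), 7, 0) + 100
  fr <- cg_frame(rbind(a, b), 300, rep(1:2, each = 6))
  traj <- trajectory_from_frames(list(fr), times = 0)
  traj$sequence <- cg_sequence("HHHHHH")
  prof <- interchain_energy_profile(traj, p)
  rij <- sqrt(outer(3.8 * (1:6), 3.8 * (1:6), "-")^2 + 49)
  e_hand <- sum(pair_energy_lj1210(rij, 0.2, 7, cutoff = p$cutoff_lj))
  expect_equal(prof$E_short, e_hand, tolerance = 1e-5)
  expect_equal(prof$E_long, 0)
})

test_that("Rg: coincident beads, rigid rod closed form, droplet sampling", {
  # all beads coincident -> 0
  fr0 <- cg_frame(matrix(5, 8, 3), 0, rep(1L, 8))
  t0 <- trajectory_from_frames(list(fr0), times = 0)
  expect_equal(rg_statistics(t0, "bulk", equil_frac = 0)$mean, 0)
  # rigid rod of N beads, spacing b: Rg = b sqrt((N^2-1)/12)
  N <- 11; b <- 3.8
  rod <- cg_frame(cbind(b * seq_len(N), 0, 0), 0, rep(1L, N))
  tr <- trajectory_from_frames(list(rod), times = 0)
  expect_equal(rg_statistics(tr, "bulk", equil_frac = 0)$mean,
               b * sqrt((N^2 - 1) / 12), tolerance = 1e-12)
})

test_that("droplet Rg distribution is broader than bulk in paired short runs", {
  tdrop <- short_droplet_run(phi = 0.2, temperature = 180, n_chains = 10,
                             n_steps = 6000, save_every = 300)
  rg_d <- rg_statistics(tdrop, "droplet")
  sq <- seq_phi(0.2)
  p <- forcefield_params(temperature = 180)
  cfg <- sim_config(n_chains = 1, n_steps = 6000, save_every = 300,
                    seed = 2, temperature = 180, box = 0, dt = 0.3)
  fr1 <- initialize_random(sq, cfg, p)
  rg_b <- rg_statistics(run_langevin(fr1, sq, cfg, p), "bulk")
  vr <- stats::var(rg_d$samples) / stats::var(rg_b$samples)
  expect_gt(vr, 1)
})
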