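#' Coarse critical-temperature estimate from short droplet-seeded runs
#'
#' Runs a droplet-initialized trajectory at each temperature of a coarse
#' grid, measures time-averaged coexistence densities and fits the
#' order-parameter scaling law. This is the scaled-down protocol used to
#' place runs at a chosen T/Tc without a full phase-diagram campaign; its
#' Tc carries the fit's extrapolation uncertainty and is meant for setting
#' temperature ratios, not as a converged critical point.
#'
#' @param sequence a [cg_sequence()].
#' @param temperatures temperature grid (K).
#' @param n_chains,n_steps,save_every scaled-down run dimensions.
#' @param seed base seed (one run per temperature, seeds `seed + 0:...`).
#' @param params base [forcefield_params()]; per-run temperature substituted.
#' @param box cubic box edge (A).
#' @param equil_frac initial fraction of frames discarded.
#' @param method `"cluster"` (default): Tc is where the largest-cluster
#'   chain fraction, a robust order parameter at small chain counts,
#'   crosses `target_fraction` (linear interpolation across the grid).
#'   `"fit"`: the coexistence scaling-law fit, appropriate when every grid
#'   point is clearly subcritical — near Tc the convex-hull density of a
#'   shrinking cluster is biased upward and can defeat the fit.
#' @param target_fraction crossing level for `method = "cluster"`.
#' @param dt integration time step.
#' @return list with `Tc`, `points` (per-temperature densities and
#'   largest-cluster fraction), `fit` (a `tc_fit` or NULL) and `method`.
#' @export
estimate_tc_quickscan <- function(sequence, temperatures = c(600, 1000, 1400, 1800),
                                  n_chains = 20L, n_steps = 12000L,
                                  save_every = 500L, seed = 1L,
                                  params = forcefield_params(), box = 300,
                                  equil_frac = 0.4,
                                  method = c("cluster", "fit"),
                                  target_fraction = 0.5, dt = 0.3) {
  method <- match.arg(method)
  rows <- list()
  for (i in seq_along(temperatures)) {
    tt <- temperatures[i]
    p <- params
    p$temperature <- tt
    cfg <- sim_config(n_chains = n_chains, n_steps = n_steps,
                      save_every = save_every, seed = seed + i - 1L,
                      init_mode = "droplet", temperature = tt, box = box,
                      dt = dt)
    fr <- minimize_frame(initialize_droplet(sequence, cfg, p), sequence, p)
    traj <- run_langevin(fr, sequence, cfg, p)
    nf <- n_frames(traj)
    keep <- seq(max(1L, floor(equil_frac * nf) + 1L), nf)
    obs <- condensate_observables(traj, frames = keep)
    rows[[i]] <- data.frame(
      temperature = tt,
      rho_dense = mean(obs$rho_dense),
      rho_dilute = mean(obs$rho_dilute),
      largest_frac = mean(obs$largest_size) / n_chains,
      weight = 1
    )
  }
  points <- do.call(rbind, rows)
  fit <- NULL
  if (method == "fit") {
    fit <- tryCatch(fit_critical_temperature(points),
                    error = function(e) NULL)
    Tc <- if (!is.null(fit)) fit$Tc else NA_real_
  } else {
    o <- order(points$temperature)
    tt <- points$temperature[o]
    fr <- points$largest_frac[o]
    below <- which(fr < target_fraction)
    if (length(below) == 0 || below[1] == 1) {
      Tc <- NA_real_  # grid entirely below (or already above) the crossing
    } else {
      k <- below[1]
      Tc <- tt[k - 1] + (tt[k] - tt[k - 1]) *
        (fr[k - 1] - target_fraction) / (fr[k - 1] - fr[k])
    }
  }
  list(Tc = Tc, points = points, fit = fit, method = method)
}

#' Droplet-to-bulk radius-of-gyration ratio at a chosen T/Tc
#'
#' The paired measurement behind the condensate-conformation comparison:
#' a droplet-initialized multi-chain run gives the dense-phase mean Rg
#' (chains resident in the largest cluster for the whole window); an
#' isolated single-chain run at the same temperature gives the bulk
#' reference. Replicate seeds are averaged.
#'
#' @param sequence a [cg_sequence()].
#' @param temperature absolute run temperature (K), typically `frac * Tc`.
#' @param n_chains droplet chain count.
#' @param n_steps steps per run.
#' @param seeds replicate seeds.
#' @param params base [forcefield_params()].
#' @param box droplet-run box edge (A).
#' @param save_every frame interval.
#' @param equil_frac initial fraction of frames discarded.
#' @return list with `ratio` (mean over seeds), `rg_droplet`, `rg_bulk`,
#'   `per_seed` data.frame.
#' @export
rg_ratio_protocol <- function(sequence, temperature, n_chains = 30L,
                              n_steps = 40000L, seeds = c(1L, 2L, 3L),
                              params = forcefield_params(), box = 300,
                              save_every = 1000L, equil_frac = 0.4) {
  p <- params
  p$temperature <- temperature
  rows <- lapply(seeds, function(s) {
    cfg <- sim_config(n_chains = n_chains, n_steps = n_steps,
                      save_every = save_every, seed = s,
                      init_mode = "droplet", temperature = temperature,
                      box = box, dt = 0.3)
    fr <- minimize_frame(initialize_droplet(sequence, cfg, p), sequence, p)
    traj <- run_langevin(fr, sequence, cfg, p)
    rg_d <- rg_statistics(traj, "droplet", equil_frac = equil_frac)
    cfg_b <- sim_config(n_chains = 1L, n_steps = n_steps,
                        save_every = max(100L, save_every %/% 4L),
                        seed = s + 1000L, temperature = temperature,
                        box = 0, dt = 0.3)
    fr_b <- initialize_random(sequence, cfg_b, p)
    traj_b <- run_langevin(fr_b, sequence, cfg_b, p)
    rg_b <- rg_statistics(traj_b, "bulk", equil_frac = equil_frac)
    data.frame(seed = s, rg_droplet = rg_d$mean, rg_bulk = rg_b$mean,
               ratio = rg_d$mean / rg_b$mean)
  })
  per_seed <- do.call(rbind, rows)
  list(ratio = mean(per_seed$ratio),
       rg_droplet = mean(per_seed$rg_droplet),
       rg_bulk = mean(per_seed$rg_bulk),
       per_seed = per_seed)
}
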