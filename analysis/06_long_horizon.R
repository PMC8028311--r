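#!/usr/bin/env Rscript

# The long-horizon comparisons across the phi series (hours on one CPU;
# not part of the default test run):
#   - fitted Tc for each phi, and the drop from phi = 0 to the minimum
#   - D_bulk/D_droplet at T = 0.4 Tc for a low-phi sequence
#   - tau_intrachain droplet/bulk ratio
#   - tau_interchain fold-change from phi = 0 to phi = 0.8 at matched T/Tc
#   - interchain energy E_total vs phi at T = 0.3 Tc (non-monotonicity)
#
# Arguments: [n_steps_scan] [n_steps_dyn]   (defaults 30000, 150000)

suppressPackageStartupMessages(library(condensim))
args <- commandArgs(trailingOnly = TRUE)
n_scan <- if (length(args) >= 1) as.integer(args[1]) else 30000L
n_dyn <- if (length(args) >= 2) as.integer(args[2]) else 150000L
dir.create("results", showWarnings = FALSE)

phis <- c(0, 0.1, 0.2, 0.4, 0.6, 0.8)
fam <- phi_series(phis = phis, seed = 1L)

## Tc across the phi series ------------------------------------------------
tc_rows <- lapply(phis, function(phi) {
  sq <- fam[[paste0("phi", phi)]]
  scan <- estimate_tc_quickscan(sq, temperatures = c(600, 1000, 1400, 1800, 2200),
                                n_chains = 20L, n_steps = n_scan,
                                save_every = n_scan %/% 25L, seed = 1L,
                                box = 300)
  message(sprintf("phi = %g: Tc ~ %.0f K", phi, scan$Tc))
  data.frame(phi = phi, Tc = scan$Tc)
})
tc_tab <- do.call(rbind, tc_rows)
write.table(tc_tab, "results/tc_vs_phi.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
drop <- 1 - min(tc_tab$Tc, na.rm = TRUE) / tc_tab$Tc[tc_tab$phi == 0]
message(sprintf("Tc drop from phi = 0 to the series minimum: %.0f%%",
                100 * drop))

## dense-phase runs at matched T/Tc ----------------------------------------
dense_run <- function(phi, t_frac, n_steps, seed = 1L) {
  sq <- fam[[paste0("phi", phi)]]
  tt <- t_frac * tc_tab$Tc[tc_tab$phi == phi]
  p <- forcefield_params(temperature = tt)
  cfg <- sim_config(n_chains = 30L, n_steps = n_steps, save_every = 200L,
                    seed = seed, init_mode = "droplet", temperature = tt,
                    box = 300, dt = 0.3)
  fr <- minimize_frame(initialize_droplet(sq, cfg, p), sq, p)
  list(traj = run_langevin(fr, sq, cfg, p), temperature = tt, p = p, sq = sq)
}
bulk_run <- function(phi, tt, n_steps, seed = 2L) {
  sq <- fam[[paste0("phi", phi)]]
  p <- forcefield_params(temperature = tt)
  cfg <- sim_config(n_chains = 1L, n_steps = n_steps, save_every = 100L,
                    seed = seed, temperature = tt, box = 0, dt = 0.3)
  run_langevin(initialize_random(sq, cfg, p), sq, cfg, p)
}

## D_bulk / D_droplet at 0.4 Tc, phi = 0.1 ---------------------------------
lowphi <- 0.1
r <- dense_run(lowphi, 0.4, n_dyn)
ass <- cluster_series(r$traj)
D_d <- diffusion_coefficient(msd_droplet(r$traj, ass))$D
tb <- bulk_run(lowphi, r$temperature, n_dyn)
D_b <- diffusion_coefficient(msd_chains(tb))$D
message(sprintf("phi = %g at 0.4 Tc: D_bulk/D_droplet = %.1f", lowphi,
                D_b / max(D_d, 1e-12)))

## tau_intra droplet vs bulk ------------------------------------------------
ti_d <- intrachain_relaxation_time(r$traj, "droplet")
ti_b <- intrachain_relaxation_time(tb, "bulk")
message(sprintf("tau_intra droplet/bulk = %s",
                if (is.na(ti_d$tau)) ">= run length (no-decay)" else
                  sprintf("%.1f", ti_d$tau / ti_b$tau)))

## tau_interchain fold change phi 0 -> 0.8 ---------------------------------
taus <- vapply(c(0, 0.8), function(phi) {
  rr <- dense_run(phi, 0.4, n_dyn)
  interchain_exchange_time(rr$traj)$tau
}, numeric(1))
message(sprintf("tau_interchain: phi0 = %.0f, phi0.8 = %.0f, fold = %.2f",
                taus[1], taus[2], taus[2] / taus[1]))

## shape anisotropy: low vs high T/Tc for low- and high-phi sequences ------
an_rows <- lapply(c(0.1, 0.8), function(phi) {
  vals <- vapply(c(0.3, 0.75), function(tf) {
    rr <- dense_run(phi, tf, n_dyn)
    nf <- n_frames(rr$traj)
    obs <- condensate_observables(rr$traj, frames = seq(nf %/% 2, nf))
    mean(obs$anisotropy, na.rm = TRUE)
  }, numeric(1))
  data.frame(phi = phi, aniso_lowT = vals[1], aniso_highT = vals[2])
})
an_tab <- do.call(rbind, an_rows)
write.table(an_tab, "results/anisotropy_vs_T.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(an_tab, row.names = FALSE)

## E_total vs phi at 0.3 Tc -------------------------------------------------
en_rows <- lapply(phis, function(phi) {
  rr <- dense_run(phi, 0.3, n_scan)
  nf <- n_frames(rr$traj)
  en <- interchain_energy_profile(rr$traj, rr$p,
                                  frames = seq(nf %/% 2, nf), per_chain = TRUE)
  data.frame(phi = phi, E_short = mean(en$E_short), E_long = mean(en$E_long),
             E_total = mean(en$E_total))
})
en_tab <- do.call(rbind, en_rows)
write.table(en_tab, "results/interchain_energy_vs_phi.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(en_tab, row.names = FALSE)

out <- list(tc_drop_percent = 100 * drop,
            D_bulk_over_droplet = D_b / max(D_d, 1e-12),
            tau_intra_ratio = ti_d$tau / ti_b$tau,
            tau_inter_fold_phi0_to_phi08 = taus[2] / taus[1])
writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null"),
           "results/long_horizon_summary.json")
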