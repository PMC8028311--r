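#!/usr/bin/env Rscript

# Liquid dynamics inside the condensate at desk scale: translational
# diffusion (droplet vs bulk, with the droplet-COM correction), the
# interchain neighbour-exchange time and the intrachain end-to-end
# relaxation time, for one sequence at one T/Tc.
#
# Arguments: [phi] [T_over_Tc] [n_steps]   (defaults 0.2, 0.5, 60000)

suppressPackageStartupMessages(library(condensim))
args <- commandArgs(trailingOnly = TRUE)
phi <- if (length(args) >= 1) as.numeric(args[1]) else 0.2
t_frac <- if (length(args) >= 2) as.numeric(args[2]) else 0.5
n_steps <- if (length(args) >= 3) as.integer(args[3]) else 60000L
dir.create("results", showWarnings = FALSE)

sq <- mutate_to_phi(build_reference_sequence(20L, 20L, 0.55, seed = 1L), phi)
scan <- estimate_tc_quickscan(sq, temperatures = c(600, 1000, 1400, 1800),
                              n_chains = 20L, n_steps = 12000L,
                              save_every = 600L, seed = 1L, box = 300)
stopifnot(!is.na(scan$Tc))
tt <- t_frac * scan$Tc
message(sprintf("phi = %g, Tc ~ %.0f K, running at T = %.0f K", phi,
                scan$Tc, tt))

p <- forcefield_params(temperature = tt)
cfg <- sim_config(n_chains = 30L, n_steps = n_steps, save_every = 200L,
                  seed = 1L, init_mode = "droplet", temperature = tt,
                  box = 300, dt = 0.3)
fr <- minimize_frame(initialize_droplet(sq, cfg, p), sq, p)
traj <- run_langevin(fr, sq, cfg, p)

ass <- cluster_series(traj)
msd_d <- msd_droplet(traj, ass)
D_d <- diffusion_coefficient(msd_d)
tau_inter <- interchain_exchange_time(traj)
tau_intra_d <- intrachain_relaxation_time(traj, "droplet")

cfg_b <- sim_config(n_chains = 1L, n_steps = n_steps, save_every = 100L,
                    seed = 2L, temperature = tt, box = 0, dt = 0.3)
traj_b <- run_langevin(initialize_random(sq, cfg_b, p), sq, cfg_b, p)
D_b <- diffusion_coefficient(msd_chains(traj_b))
tau_intra_b <- intrachain_relaxation_time(traj_b, "bulk")

fmt_tau <- function(x) if (is.na(x$tau)) "no-decay" else sprintf("%.0f", x$tau)
message(sprintf("D_droplet = %.3g, D_bulk = %.3g, ratio D_d/D_b = %.3g",
                D_d$D, D_b$D, D_d$D / D_b$D))
message(sprintf("tau_interchain = %s, tau_intrachain(droplet) = %s, tau_intrachain(bulk) = %s (time units)",
                fmt_tau(tau_inter), fmt_tau(tau_intra_d), fmt_tau(tau_intra_b)))

out <- list(phi = phi, T_over_Tc = t_frac, Tc = scan$Tc, T = tt,
            D_droplet = D_d$D, D_bulk = D_b$D,
            D_ratio = D_d$D / D_b$D,
            tau_interchain = tau_inter$tau,
            tau_intrachain_droplet = tau_intra_d$tau,
            tau_intrachain_bulk = tau_intra_b$tau,
            tau_method = tau_inter$method)
writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null"),
           sprintf("results/dynamics_phi%s_T%s.json", phi, t_frac))
write.table(data.frame(lag = msd_d$lag, msd = msd_d$msd, n = msd_d$n),
            sprintf("results/msd_droplet_phi%s.tsv", phi),
            sep = "\t", row.names = FALSE, quote = FALSE)
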