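#' Define an experiment plan
#'
#' A plan is the full factorial of sequences (by hydrophobic fraction),
#' short-range interaction strengths, temperatures and replicate seeds.
#' The `"paper"` preset records the study-scale protocol (100 chains, 1e7
#' steps, random initialization, phi grid 0-0.8 and epsilon grid
#' 0.0-0.5); the `"desk"` preset is the scaled-down protocol used for
#' interactive work and testing (30 chains, 1e5 steps, droplet
#' initialization).
#'
#' @param phis hydrophobic fractions (sequences built via [phi_series()]).
#' @param eps_lj short-range strengths to sweep.
#' @param temperatures temperature grid (K).
#' @param seeds replicate seeds.
#' @param scale `"desk"` or `"paper"` preset.
#' @param out_root run-directory root (created on demand by [run_plan()]).
#' @param n_chains,n_steps,save_every,init_mode overrides of the preset.
#' @return list of class `experiment_plan` with a `tuples` data.frame (one
#'   row per run).
#' @export
experiment_plan <- function(phis = c(0, 0.2), eps_lj = 0.2,
                            temperatures = c(200, 250, 300),
                            seeds = 1L, scale = c("desk", "paper"),
                            out_root = "runs",
                            n_chains = NULL, n_steps = NULL,
                            save_every = NULL, init_mode = NULL) {
  scale <- match.arg(scale)
  preset <- if (scale == "paper") {
    list(n_chains = 100L, n_steps = 1e7, save_every = 5000L,
         init_mode = "random",
         phis = c(0, 0.05, 0.1, 0.2, 0.4, 0.5, 0.6, 0.8),
         eps_grid = c(0.0, 0.2, 0.3, 0.4, 0.5))
  } else {
    list(n_chains = 30L, n_steps = 1e5, save_every = 500L,
         init_mode = "droplet",
         phis = phis, eps_grid = eps_lj)
  }
  if (scale == "paper") {
    phis <- preset$phis
    if (missing(eps_lj)) eps_lj <- 0.2
  }
  tuples <- expand.grid(phi = phis, eps_lj = eps_lj,
                        temperature = temperatures, seed = seeds,
                        KEEP.OUT.ATTRS = FALSE)
  tuples$run_id <- sprintf("phi%s_eps%s_T%s_seed%d", tuples$phi,
                           tuples$eps_lj, tuples$temperature, tuples$seed)
  structure(
    list(
      tuples = tuples, scale = scale, out_root = out_root,
      n_chains = as.integer(n_chains %||% preset$n_chains),
      n_steps = as.integer(n_steps %||% preset$n_steps),
      save_every = as.integer(save_every %||% preset$save_every),
      init_mode = init_mode %||% preset$init_mode,
      paper_phi_grid = c(0, 0.05, 0.1, 0.2, 0.4, 0.5, 0.6, 0.8),
      paper_eps_grid = c(0.0, 0.2, 0.3, 0.4, 0.5)
    ),
    class = "experiment_plan"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute an experiment plan
#'
#' Runs simulate -> condensate detection -> thermodynamics -> dynamics for
#' every (phi, epsilon, T, seed) tuple, writing per-run observables under
#' `plan$out_root/<run_id>/` and returning one merged observable table.
#' Completed tuples (whose `observables.tsv` already exists) are skipped,
#' so interrupted sweeps resume; per-tuple failures are logged and
#' quarantined without aborting the sweep.
#'
#' @param plan an [experiment_plan()].
#' @param params base [forcefield_params()] (per-tuple `eps_lj` and
#'   `temperature` are substituted).
#' @param dynamics also compute diffusion and relaxation times per run.
#' @param verbose print one line per tuple.
#' @return invisibly, a data.frame with one row per (tuple, observable):
#'   columns `run_id`, `phi`, `eps_lj`, `temperature`, `seed`,
#'   `observable`, `value`. Also written to `plan$out_root/merged.tsv`.
#' @export
run_plan <- function(plan, params = forcefield_params(), dynamics = FALSE,
                     verbose = TRUE) {
  dir.create(plan$out_root, showWarnings = FALSE, recursive = TRUE)
  seqs <- phi_series(phis = sort(unique(plan$tuples$phi)))
  rows <- list()
  for (i in seq_len(nrow(plan$tuples))) {
    tup <- plan$tuples[i, ]
    run_dir <- file.path(plan$out_root, tup$run_id)
    obs_file <- file.path(run_dir, "observables.tsv")
    if (file.exists(obs_file)) {
      if (verbose) message("skip (done): ", tup$run_id)
      rows[[i]] <- utils::read.delim(obs_file)
      next
    }
    res <- tryCatch({
      dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
      sq <- seqs[[paste0("phi", tup$phi)]]
      p <- params
      p$eps_lj <- tup$eps_lj
      p$temperature <- tup$temperature
      cfg <- sim_config(
        n_chains = plan$n_chains, n_steps = plan$n_steps,
        save_every = plan$save_every, seed = tup$seed,
        init_mode = plan$init_mode, temperature = tup$temperature
      )
      fr <- if (plan$init_mode == "droplet") {
        initialize_droplet(sq, cfg, p)
      } else {
        initialize_random(sq, cfg, p)
      }
      traj <- run_langevin(fr, sq, cfg, p)
      nf <- n_frames(traj)
      keep <- seq(max(1L, floor(0.3 * nf) + 1L), nf)
      obs <- condensate_observables(traj, frames = keep)
      en <- interchain_energy_profile(traj, p, frames = keep,
                                      per_chain = TRUE)
      vals <- c(
        rho_dense = mean(obs$rho_dense),
        rho_dilute = mean(obs$rho_dilute),
        largest_size = mean(obs$largest_size),
        anisotropy = mean(obs$anisotropy, na.rm = TRUE),
        E_short = mean(en$E_short), E_long = mean(en$E_long),
        E_total = mean(en$E_total)
      )
      if (dynamics) {
        ass <- cluster_series(traj)
        dcurve <- msd_chains(traj, assignments = ass)
        vals <- c(vals,
          D_droplet = tryCatch(diffusion_coefficient(dcurve)$D,
                               error = function(e) NA_real_),
          tau_inter = tryCatch(interchain_exchange_time(traj)$tau,
                               error = function(e) NA_real_),
          tau_intra = tryCatch(
            intrachain_relaxation_time(traj, "droplet")$tau,
            error = function(e) NA_real_))
      }
      out <- data.frame(
        run_id = tup$run_id, phi = tup$phi, eps_lj = tup$eps_lj,
        temperature = tup$temperature, seed = tup$seed,
        observable = names(vals), value = unname(vals)
      )
      utils::write.table(out, obs_file, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      per_frame <- file.path(run_dir, "per_frame.tsv")
      utils::write.table(obs, per_frame, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      if (verbose) message("done: ", tup$run_id)
      out
    }, error = function(e) {
      msg <- conditionMessage(e)
      writeLines(msg, file.path(run_dir, "FAILED"))
      warning("tuple ", tup$run_id, " failed: ", msg)
      NULL
    })
    rows[[i]] <- res
  }
  merged <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  utils::write.table(merged, file.path(plan$out_root, "merged.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(merged)
}

#' Convergence diagnostics across replicate trajectories
#'
#' For each replicate, the time evolution of the dense-phase density and
#' of the chain mean-squared displacement, plus a stationarity flag from a
#' Kendall trend test on the final half of the density series.
#'
#' @param trajs list of `cg_trajectory` replicates (>= 1).
#' @param alpha significance level of the trend test.
#' @return list with `density` (data.frame: replicate, time, rho_dense),
#'   `msd` (data.frame: replicate, lag, msd) and `stationary` (logical per
#'   replicate).
#' @export
convergence_report <- function(trajs, alpha = 0.05) {
  stopifnot(length(trajs) >= 1)
  dens <- list(); msds <- list(); flags <- logical(length(trajs))
  for (r in seq_along(trajs)) {
    traj <- trajs[[r]]
    obs <- condensate_observables(traj)
    dens[[r]] <- data.frame(replicate = r, time = obs$time,
                            rho_dense = obs$rho_dense)
    curve <- msd_chains(traj)
    msds[[r]] <- data.frame(replicate = r, lag = curve$lag, msd = curve$msd)
    half <- obs$rho_dense[seq(ceiling(nrow(obs) / 2), nrow(obs))]
    if (length(half) >= 5 && stats::sd(half) > 0) {
      kt <- suppressWarnings(
        stats::cor.test(seq_along(half), half, method = "kendall"))
      flags[r] <- !(kt$p.value < alpha && abs(kt$estimate) > 0.5)
    } else {
      flags[r] <- TRUE  # constant series is trivially stationary
    }
  }
  list(density = do.call(rbind, dens), msd = do.call(rbind, msds),
       stationary = flags)
}
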