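# Shared fixtures: tiny sequences, frames and short-run helpers.

seq_ref <- function() build_reference_sequence(20L, 20L, 0.55, seed = 1L)

seq_phi <- function(phi) mutate_to_phi(seq_ref(), phi)

# a hand-sized frame: `k` chains of `n` beads on a loose grid, no contacts
frame_dispersed <- function(k = 3, n = 5, box = 200, spacing = 50) {
  pos <- do.call(rbind, lapply(seq_len(k), function(c) {
    cbind(seq_len(n) * 3.8 + c * spacing, c * spacing / 2, c * spacing / 3)
  }))
  cg_frame(pos, box, rep(seq_len(k), each = n))
}

# brute-force reachability: connected components by repeated set expansion
components_bruteforce <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

# all distinct charge arrangements of n_pos +1 and n_neg -1 (labels)
all_arrangements <- function(n_pos, n_neg) {
  n <- n_pos + n_neg
  pos_sets <- utils::combn(n, n_pos, simplify = FALSE)
  lapply(pos_sets, function(ix) {
    lab <- rep("-", n)
    lab[ix] <- "+"
    lab
  })
}

# quick dense-phase run used by several slower tests
short_droplet_run <- function(phi = 0.2, temperature = 200, n_chains = 12,
                              n_steps = 4000, seed = 1, save_every = 200,
                              eps_lj = 0.2) {
  sq <- seq_phi(phi)
  p <- forcefield_params(temperature = temperature, eps_lj = eps_lj)
  cfg <- sim_config(n_chains = n_chains, n_steps = n_steps,
                    save_every = save_every, seed = seed,
                    init_mode = "droplet", temperature = temperature,
                    box = 200, dt = 0.3)
  fr <- minimize_frame(initialize_droplet(sq, cfg, p), sq, p)
  run_langevin(fr, sq, cfg, p)
}
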