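#' Synthetic droplet + gas configuration with known geometry
#'
#' Builds a frame with `n_dense_chains` packed uniformly inside an
#' ellipsoid centred in the box and `n_gas_chains` placed uniformly in the
#' remaining volume — a fixture with planted densities and shape for
#' testing condensate detection. With `chain_length = 1` beads are drawn
#' exactly uniformly; for longer chains each chain is a compact random
#' walk around a uniform centre, so the bead density is uniform up to edge
#' effects.
#'
#' @param n_dense_chains,n_gas_chains chain counts in the two phases.
#' @param chain_length beads per chain.
#' @param droplet_axes semi-axes (a, b, c) of the ellipsoid (A).
#' @param box cubic box edge (A).
#' @param seed integer seed.
#' @param bond_length walk step for `chain_length > 1`.
#' @return a [cg_frame()] with attribute `ground_truth`: list with the
#'   planted `rho_dense`, `rho_dilute`, `axes`, `anisotropy` and chain
#'   index sets.
#' @export
gen_droplet_config <- function(n_dense_chains, n_gas_chains, chain_length,
                               droplet_axes, box, seed = 1L,
                               bond_length = 3.8) {
  stopifnot(all(2 * droplet_axes < box))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  centre <- rep(box / 2, 3)
  ax <- rep(droplet_axes, length.out = 3)

  runif_ellipsoid <- function() {
    repeat {
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) <= 1) return(centre + u * ax)
    }
  }
  runif_gas <- function() {
    repeat {
      p <- stats::runif(3, 0, box)
      if (sum(((p - centre) / ax)^2) > 1.1) return(p)
    }
  }
  place <- function(n_chains, sampler, confine) {
    out <- matrix(NA_real_, n_chains * chain_length, 3)
    row <- 1L
    for (c in seq_len(n_chains)) {
      p0 <- sampler()
      out[row, ] <- p0
      prev <- p0
      if (chain_length > 1) {
        for (k in 2:chain_length) {
          repeat {
            u <- stats::rnorm(3)
            cand <- prev + bond_length * u / sqrt(sum(u^2))
            inside <- sum(((cand - centre) / ax)^2) <= 1
            if (confine == "in" && inside) break
            if (confine == "out" && !inside) break
          }
          out[row + k - 1L, ] <- cand
          prev <- cand
        }
      }
      row <- row + chain_length
    }
    out
  }
  dense <- if (n_dense_chains > 0) place(n_dense_chains, runif_ellipsoid, "in")
  gas <- if (n_gas_chains > 0) place(n_gas_chains, runif_gas, "out")
  pos <- rbind(dense, gas)
  nch <- n_dense_chains + n_gas_chains
  fr <- cg_frame(pos, box, rep(seq_len(nch), each = chain_length))
  v_ell <- 4 / 3 * pi * prod(ax)
  d <- 2 * ax
  attr(fr, "ground_truth") <- list(
    rho_dense = n_dense_chains * chain_length / v_ell,
    rho_dilute = n_gas_chains * chain_length / (box^3 - v_ell),
    axes = ax,
    anisotropy = d[1] / d[2] + d[2] / d[3] + d[3] / d[1],
    dense_chains = seq_len(n_dense_chains),
    gas_chains = setdiff(seq_len(nch), seq_len(n_dense_chains)),
    seed = seed
  )
  fr
}

#' Brownian walkers with known diffusion coefficient
#'
#' Independent particles taking Gaussian steps of variance `2 D_true dt`
#' per axis, plus an optional uniform drift — the oracle for the MSD and
#' diffusion estimators (the drift emulates droplet centre-of-mass
#' motion).
#'
#' @param n_particles walker count.
#' @param D_true diffusion coefficient (A^2 per time unit).
#' @param n_steps number of saved steps.
#' @param dt time between saves.
#' @param drift length-3 drift velocity (A per time unit).
#' @param seed integer seed.
#' @param box optional periodic box (`<= 0` for none).
#' @return a `cg_trajectory` of single-bead chains with attribute
#'   `ground_truth` (`D_true`, `drift`, `seed`).
#' @export
gen_brownian <- function(n_particles, D_true, n_steps, dt = 1,
                         drift = c(0, 0, 0), seed = 1L, box = 0) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sd_step <- sqrt(2 * D_true * dt)
  pos <- array(NA_real_, c(n_particles, 3, n_steps))
  start_span <- if (box > 0) box else 100
  pos[, , 1] <- matrix(stats::runif(n_particles * 3, 0, start_span),
                       n_particles, 3)
  for (k in 2:n_steps) {
    step <- matrix(stats::rnorm(n_particles * 3, sd = sd_step),
                   n_particles, 3)
    pos[, , k] <- pos[, , k - 1] + step +
      matrix(drift * dt, n_particles, 3, byrow = TRUE)
  }
  if (box > 0) pos <- pos - box * floor(pos / box)
  traj <- structure(
    list(positions = pos, times = (seq_len(n_steps) - 1) * dt, box = box,
         chain_index = seq_len(n_particles),
         energy_log = NULL, kinetic_T = NULL, velocities = NULL,
         sequence = NULL, config = NULL, params = NULL, seed = seed),
    class = "cg_trajectory"
  )
  attr(traj, "ground_truth") <- list(D_true = D_true, drift = drift,
                                     seed = seed)
  traj
}

#' Ornstein-Uhlenbeck series with known relaxation time
#'
#' Exact-discretization updates
#' x(t+dt) = mu + (x(t) - mu) e^(-dt/tau) + sqrt(v (1 - e^(-2 dt/tau))) xi,
#' started from the stationary distribution, so the autocorrelation is
#' exactly exp(-t/tau) at every lag — the oracle for the intrachain
#' relaxation estimator.
#'
#' @param tau_true relaxation time.
#' @param variance stationary variance.
#' @param n_steps series length.
#' @param dt time spacing.
#' @param seed integer seed.
#' @param mean_level stationary mean (default 10, an end-to-end-like level).
#' @return numeric series with attribute `ground_truth`.
#' @export
gen_ou_series <- function(tau_true, variance, n_steps, dt = 1, seed = 1L,
                          mean_level = 10) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  a <- exp(-dt / tau_true)
  s <- sqrt(variance * (1 - a^2))
  x <- numeric(n_steps)
  x[1] <- mean_level + stats::rnorm(1, sd = sqrt(variance))
  for (k in 2:n_steps) {
    x[k] <- mean_level + (x[k - 1] - mean_level) * a + s * stats::rnorm(1)
  }
  attr(x, "ground_truth") <- list(tau_true = tau_true, variance = variance,
                                  dt = dt, seed = seed)
  x
}

#' Two-state telegraph (contact) series with known switching rate
#'
#' A symmetric two-state Markov process switching between 0 and 1 at rate
#' `k_switch` per state, sampled every `dt` with the exact transition
#' probability p = (1 - e^(-2 k dt))/2, so the centred autocorrelation is
#' exactly exp(-2 k t) and the relaxation time 1/(2 k).
#'
#' @param k_switch switching rate per state (1/time unit).
#' @param n_steps series length.
#' @param dt sampling interval.
#' @param seed integer seed.
#' @return integer 0/1 series with attribute `ground_truth` (including
#'   `tau_true = 1/(2 k_switch)`).
#' @export
gen_telegraph <- function(k_switch, n_steps, dt = 1, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p_flip <- (1 - exp(-2 * k_switch * dt)) / 2
  h <- integer(n_steps)
  h[1] <- stats::rbinom(1, 1, 0.5)
  flips <- stats::runif(n_steps - 1) < p_flip
  for (k in 2:n_steps) h[k] <- if (flips[k - 1]) 1L - h[k - 1] else h[k - 1]
  attr(h, "ground_truth") <- list(
    k_switch = k_switch,
    tau_true = if (k_switch > 0) 1 / (2 * k_switch) else Inf,
    dt = dt, seed = seed
  )
  h
}

#' Coexistence curve drawn from the critical scaling law
#'
#' Phase points with rho_dense - rho_dilute = A (1 - T/Tc_true)^beta around
#' a mid-density `rho_c`, with optional additive Gaussian noise — the
#' oracle for the Tc fit. `reentrant = TRUE` deforms the dense branch at
#' low temperature (density dropping below the peak) for detector tests.
#'
#' @param Tc_true critical temperature (K).
#' @param A order-parameter amplitude (beads/A^3).
#' @param beta critical exponent.
#' @param n_points number of temperatures (spread over 0.5-0.95 Tc).
#' @param noise_sd standard deviation of additive density noise.
#' @param seed integer seed.
#' @param rho_c mid density.
#' @param reentrant plant a re-entrant dense branch.
#' @return data.frame with `temperature`, `rho_dense`, `rho_dilute` and
#'   attribute `ground_truth`.
#' @export
gen_coexistence_curve <- function(Tc_true, A, beta = 0.325, n_points = 8,
                                  noise_sd = 0, seed = 1L, rho_c = A / 2,
                                  reentrant = FALSE) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tt <- Tc_true * seq(0.5, 0.95, length.out = n_points)
  drho <- A * (1 - tt / Tc_true)^beta
  dense <- rho_c + drho / 2
  dilute <- pmax(rho_c - drho / 2, 0)
  if (reentrant) {
    # suppress the dense branch below 0.65 Tc: density peaks, then falls
    low <- tt < 0.65 * Tc_true
    fade <- (tt[low] / (0.65 * Tc_true))^3
    dense[low] <- dense[low] * fade
  }
  if (noise_sd > 0) {
    dense <- dense + stats::rnorm(n_points, sd = noise_sd)
    dilute <- pmax(dilute + stats::rnorm(n_points, sd = noise_sd), 0)
  }
  out <- data.frame(temperature = tt, rho_dense = dense, rho_dilute = dilute)
  attr(out, "ground_truth") <- list(Tc_true = Tc_true, A = A, beta = beta,
                                    noise_sd = noise_sd, seed = seed,
                                    reentrant = reentrant)
  out
}
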