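#' Force-field parameter set
#'
#' Collects every interaction constant of the coarse-grained model in one
#' list. Units: energies in kcal/mol, lengths in Angstrom, temperatures in
#' Kelvin, kB = 0.0019872 kcal/mol/K. The defaults reproduce the model's
#' stated parameterization: 12-10 dispersion well depth `eps_lj` = 0.2 at
#' `sigma_lj` = 7 A between hydrophobic beads, r^-12 excluded volume with
#' `sigma_rep` = 4 A, Debye-Hueckel electrostatics with dielectric 80,
#' `K_coulomb` = 332 kcal A/mol and 0.02 M monovalent salt.
#'
#' @param eps_lj dispersion well depth (kcal/mol) between hydrophobic beads.
#' @param sigma_lj dispersion optimal distance (A).
#' @param eps_rep excluded-volume prefactor (kcal/mol); the model paper
#'   leaves it unstated, 0.2 is the package default.
#' @param sigma_rep excluded-volume length scale (A).
#' @param dielectric solvent dielectric constant.
#' @param K_coulomb Coulomb constant, 332 kcal A/mol.
#' @param salt_I monovalent ionic strength (mol/L).
#' @param ion_radius_a ion radius entering the finite-ion-size factor
#'   B(kappa) = exp(kappa a)/(1 + kappa a).
#' @param temperature temperature (K) used for the Debye screening length.
#' @param k_bond,r0_bond harmonic bond constant (kcal/mol/A^2) and rest
#'   length (A; 3.8 A Calpha-Calpha spacing).
#' @param k_angle,theta0 harmonic angle constant (kcal/mol/rad^2) and rest
#'   angle; `angles_on = FALSE` removes the angle term entirely (the fully
#'   flexible reading).
#' @param angles_on logical; include the angle term.
#' @param cutoff_dh electrostatics cutoff (A); default 1.6 Debye lengths at
#'   the given salt/temperature, capped at 45 A. Beyond this range the
#'   screened pair energy is a few percent of kBT and, because the solution
#'   is net-neutral, tail contributions largely cancel; see the methods
#'   vignette.
#' @param cutoff_lj cutoff (A) for the dispersion and excluded-volume terms.
#' @param shift_at_cutoff logical; shift each nonbonded term to zero at its
#'   cutoff (removes the truncation discontinuity; used for
#'   constant-energy integration checks).
#' @param repulsion_on_all_pairs logical; if `FALSE` (default) the r^-12
#'   excluded volume is not added between hydrophobic pairs, whose 12-10
#'   term already carries a repulsive core; `TRUE` applies it to every
#'   nonbonded pair (the literal reading).
#' @param kB Boltzmann constant in kcal/mol/K.
#' @return a list of class `ff_params`.
#' @export
#' @examples
#' p <- forcefield_params()
#' 1 / debye_kappa(p$salt_I, p$temperature, p$dielectric)  # Debye length, A
forcefield_params <- function(eps_lj = 0.2, sigma_lj = 7,
                              eps_rep = 0.2, sigma_rep = 4,
                              dielectric = 80, K_coulomb = 332,
                              salt_I = 0.02, ion_radius_a = 5.24,
                              temperature = 300,
                              k_bond = 20, r0_bond = 3.8,
                              k_angle = 2, theta0 = 2 * pi / 3,
                              angles_on = TRUE,
                              cutoff_dh = NULL, cutoff_lj = 25,
                              repulsion_on_all_pairs = FALSE,
                              shift_at_cutoff = FALSE,
                              kB = 0.0019872) {
  stopifnot(
    sigma_lj > 0, sigma_rep > 0, r0_bond > 0, eps_lj >= 0, eps_rep >= 0,
    dielectric > 0, salt_I >= 0, temperature > 0, cutoff_lj >= sigma_lj
  )
  if (is.null(cutoff_dh)) {
    kap <- debye_kappa(salt_I, temperature, dielectric)
    cutoff_dh <- if (kap > 0) min(1.6 / kap, 45) else 45
  }
  stopifnot(cutoff_dh > 0)
  structure(
    list(
      eps_lj = eps_lj, sigma_lj = sigma_lj,
      eps_rep = eps_rep, sigma_rep = sigma_rep,
      dielectric = dielectric, K_coulomb = K_coulomb,
      salt_I = salt_I, ion_radius_a = ion_radius_a,
      temperature = temperature,
      k_bond = k_bond, r0_bond = r0_bond,
      k_angle = k_angle, theta0 = theta0, angles_on = angles_on,
      cutoff_dh = cutoff_dh, cutoff_lj = cutoff_lj,
      repulsion_on_all_pairs = repulsion_on_all_pairs,
      shift_at_cutoff = shift_at_cutoff,
      kB = kB
    ),
    class = "ff_params"
  )
}

#' Inverse Debye screening length
#'
#' From the Poisson-Boltzmann relation for a 1:1 salt,
#' kappa^2 = 8 pi l_B n_I with Bjerrum length
#' l_B = K_coulomb / (dielectric kB T) and ion number density
#' n_I = I N_A 1e-27 per A^3.
#'
#' @param salt_I ionic strength (mol/L); 0 gives the unscreened Coulomb limit.
#' @param temperature Kelvin.
#' @param dielectric solvent dielectric constant.
#' @param K_coulomb,kB constants, see [forcefield_params()].
#' @return kappa in 1/A.
#' @export
debye_kappa <- function(salt_I, temperature = 300, dielectric = 80,
                        K_coulomb = 332, kB = 0.0019872) {
  if (any(salt_I < 0)) stop("ionic strength must be non-negative")
  l_bjerrum <- K_coulomb / (dielectric * kB * temperature)
  n_ion <- salt_I * 6.02214076e-4  # ions per A^3 per species pair, I in mol/L
  sqrt(8 * pi * l_bjerrum * n_ion)
}

dh_B <- function(kappa, a) exp(kappa * a) / (1 + kappa * a)

#' Screened electrostatic pair energy (Debye-Hueckel)
#'
#' U(r) = K_coulomb B(kappa) q_i q_j exp(-kappa r) / (dielectric r), zero
#' beyond `params$cutoff_dh`. B(kappa) = exp(kappa a)/(1 + kappa a) is the
#' finite-ion-size salt correction.
#'
#' @param q_i,q_j bead charges (elementary units).
#' @param r pair distance(s), A; must be positive.
#' @param params a [forcefield_params()].
#' @return energy in kcal/mol (vectorized over `r`).
#' @export
pair_energy_dh <- function(q_i, q_j, r, params = forcefield_params()) {
  if (any(r <= 0)) stop("singular pair: r must be > 0")
  kap <- debye_kappa(params$salt_I, params$temperature, params$dielectric,
                     params$K_coulomb, params$kB)
  a <- params$ion_radius_a
  e <- params$K_coulomb * q_i * q_j * exp(kap * (a - r)) /
    ((1 + kap * a) * params$dielectric * r)
  e[r > params$cutoff_dh] <- 0
  e
}

#' 12-10 Lennard-Jones dispersion pair energy
#'
#' U(r) = eps [5 (sigma/r)^12 - 6 (sigma/r)^10]; minimum value -eps at
#' r = sigma, zero crossing at sigma sqrt(5/6).
#'
#' @param r pair distance(s), A; must be positive.
#' @param eps_lj well depth (kcal/mol).
#' @param sigma_lj optimal distance (A).
#' @param cutoff energies are zero beyond this distance (default none).
#' @return energy in kcal/mol (vectorized over `r`).
#' @export
pair_energy_lj1210 <- function(r, eps_lj = 0.2, sigma_lj = 7, cutoff = Inf) {
  if (any(r <= 0)) stop("singular pair: r must be > 0")
  x <- sigma_lj / r
  e <- eps_lj * (5 * x^12 - 6 * x^10)
  e[r > cutoff] <- 0
  e
}

#' Excluded-volume r^-12 pair energy
#'
#' U(r) = eps_rep (sigma_rep / r)^12; strictly positive and decreasing.
#'
#' @param r pair distance(s), A; must be positive.
#' @param eps_rep prefactor (kcal/mol).
#' @param sigma_rep length scale (A).
#' @param cutoff zero beyond this distance (default none).
#' @return energy in kcal/mol (vectorized over `r`).
#' @export
pair_energy_repulsion <- function(r, eps_rep = 0.2, sigma_rep = 4, cutoff = Inf) {
  if (any(r <= 0)) stop("singular pair: r must be > 0")
  e <- eps_rep * (sigma_rep / r)^12
  e[r > cutoff] <- 0
  e
}

bead_types <- function(sequence, n_chains) {
  list(
    charge = rep(as.numeric(sequence$charge), n_chains),
    hydrophobic = rep(sequence$hydrophobic, n_chains)
  )
}

params_for_cpp <- function(params, sequence, frame) {
  n_chains <- length(unique(frame$chain_index))
  ty <- bead_types(sequence, n_chains)
  if (length(ty$charge) != nrow(frame$positions)) {
    stop("sequence length x chain count does not match bead count")
  }
  kap <- debye_kappa(params$salt_I, params$temperature, params$dielectric,
                     params$K_coulomb, params$kB)
  list(
    charge = ty$charge, hydro = as.integer(ty$hydrophobic),
    chain = as.integer(frame$chain_index) - 1L,
    kappa_dh = kap, dh_a = params$ion_radius_a,
    # K/(dielectric (1+kappa a)); exp(kappa a) is folded into the pair
    # exponential as exp(kappa (a - r)) to keep extreme screening finite
    dh_pref = params$K_coulomb / (params$dielectric * (1 + kap * params$ion_radius_a)),
    eps_lj = params$eps_lj, sigma_lj = params$sigma_lj,
    eps_rep = params$eps_rep, sigma_rep = params$sigma_rep,
    cutoff_dh = params$cutoff_dh, cutoff_lj = params$cutoff_lj,
    k_bond = params$k_bond, r0_bond = params$r0_bond,
    k_angle = if (params$angles_on) params$k_angle else 0,
    theta0 = params$theta0,
    rep_all = as.integer(params$repulsion_on_all_pairs),
    shift_at_cutoff = as.integer(isTRUE(params$shift_at_cutoff))
  )
}

#' Total potential energy with intra-/inter-chain breakdown
#'
#' Sums harmonic bonds and angles along each chain, Debye-Hueckel energies
#' over charged pairs, 12-10 dispersion over hydrophobic pairs and the
#' r^-12 excluded volume (eligibility controlled by
#' `repulsion_on_all_pairs`), excluding 1-2 and 1-3 neighbours along a
#' chain from the nonbonded terms, under the minimum-image convention.
#'
#' @param frame a `cg_frame` (see [initialize_random()]).
#' @param sequence the [cg_sequence()] shared by all chains in the frame.
#' @param params a [forcefield_params()].
#' @return a list of class `energy_breakdown` with components `bond`,
#'   `angle`, `dh_intra`, `dh_inter`, `lj_intra`, `lj_inter`, `rep_intra`,
#'   `rep_inter` and `total`.
#' @export
total_energy <- function(frame, sequence, params = forcefield_params()) {
  p <- params_for_cpp(params, sequence, frame)
  res <- energy_forces_cpp(frame$positions, frame$box, p, FALSE)
  e <- res$energy
  names(e) <- c("bond", "angle", "dh_intra", "dh_inter",
                "lj_intra", "lj_inter", "rep_intra", "rep_inter")
  out <- as.list(e)
  out$total <- sum(e)
  if (res$min_dist < 0.5) {
    warning(sprintf("overlapping beads: minimum pair distance %.3f A", res$min_dist))
  }
  structure(out, class = "energy_breakdown")
}

#' Per-bead forces
#'
#' The negative gradient of [total_energy()] with respect to every bead
#' coordinate. In the absence of external fields the forces sum to zero.
#'
#' @inheritParams total_energy
#' @return an n x 3 matrix of forces (kcal/mol/A).
#' @export
forces <- function(frame, sequence, params = forcefield_params()) {
  p <- params_for_cpp(params, sequence, frame)
  energy_forces_cpp(frame$positions, frame$box, p, TRUE)$forces
}
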