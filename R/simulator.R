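#' Simulation configuration
#'
#' Internal units: lengths in Angstrom, energies in kcal/mol, bead mass
#' `mass` in g/mol; the time unit is sqrt(mass A^2 / (kcal/mol)) (about
#' 48.9 fs for unit mass). With the default bead mass of 100 g/mol the
#' stiffest term (bonds, k = 20 kcal/mol/A^2) has angular frequency 0.63
#' per time unit, so the default `dt = 0.2` resolves it comfortably.
#'
#' @param n_chains number of chains.
#' @param n_steps number of integration steps.
#' @param dt time step (reduced time units).
#' @param gamma Langevin friction (1/time unit); low friction keeps
#'   sampling efficient while the BAOAB scheme thermostats exactly.
#' @param save_every save a frame every this many steps.
#' @param seed integer seed (one generator per trajectory).
#' @param init_mode `"random"` (dispersed chains) or `"droplet"`
#'   (pre-assembled condensate, for scaled-down dense-phase runs).
#' @param temperature target temperature (K).
#' @param box cubic box edge (A); `box <= 0` disables periodic boundaries
#'   (used for single-chain bulk references).
#' @param mass bead mass (g/mol).
#' @param skin neighbour-list skin (A).
#' @param droplet_radius initial droplet radius (A) for `init_mode = "droplet"`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chains = 100L, n_steps = 1e5L, dt = 0.2,
                       gamma = 0.05, save_every = 500L, seed = 1L,
                       init_mode = c("random", "droplet"),
                       temperature = 300, box = 300, mass = 100,
                       skin = 4, droplet_radius = NULL) {
  init_mode <- match.arg(init_mode)
  stopifnot(dt > 0, n_steps >= 1, n_chains >= 1, save_every >= 1,
            temperature > 0)
  structure(
    list(
      n_chains = as.integer(n_chains), n_steps = as.integer(n_steps),
      dt = dt, gamma = gamma, save_every = as.integer(save_every),
      seed = as.integer(seed), init_mode = init_mode,
      temperature = temperature, box = box, mass = mass, skin = skin,
      droplet_radius = droplet_radius
    ),
    class = "sim_config"
  )
}

#' Construct a frame
#'
#' @param positions n x 3 coordinate matrix (A).
#' @param box cubic box edge (A); `<= 0` for no periodic boundaries.
#' @param chain_index integer chain id per bead (1-based).
#' @param time time stamp.
#' @return list of class `cg_frame`.
#' @export
cg_frame <- function(positions, box, chain_index, time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)),
            length(chain_index) == nrow(positions))
  structure(
    list(positions = positions, box = box,
         chain_index = as.integer(chain_index), time = time),
    class = "cg_frame"
  )
}

#' @export
print.cg_frame <- function(x, ...) {
  cat(sprintf("<cg_frame> %d beads, %d chains, box %.1f A, t = %g\n",
              nrow(x$positions), length(unique(x$chain_index)), x$box, x$time))
  invisible(x)
}

# grow one chain as a self-avoiding random walk; `existing` holds previously
# placed bead coordinates (possibly NULL)
grow_chain <- function(n_res, r0, start, box, existing, min_dist = 3,
                       confine_centre = NULL, confine_radius = Inf,
                       max_tries = 200L) {
  pos <- matrix(NA_real_, n_res, 3)
  pos[1, ] <- start
  for (k in 2:n_res) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      u <- stats::rnorm(3)
      step <- r0 * u / sqrt(sum(u^2))
      cand <- pos[k - 1, ] + step
      if (is.finite(confine_radius)) {
        if (sqrt(sum((cand - confine_centre)^2)) > confine_radius) next
      }
      prev <- pos[seq_len(k - 2), , drop = FALSE]  # own beads except bonded one
      chk <- rbind(prev, existing)
      if (!is.null(chk) && nrow(chk) > 0) {
        d <- sweep(chk, 2, cand)
        if (box > 0) d <- d - box * round(d / box)
        if (min(rowSums(d^2)) < min_dist^2) next
      }
      pos[k, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  pos
}

place_chains <- function(sequence, n_chains, box, r0, min_dist = 3,
                         centre = NULL, radius = Inf, max_retries = 50L) {
  n_res <- sequence$length
  all_pos <- NULL
  for (c in seq_len(n_chains)) {
    done <- FALSE
    for (retry in seq_len(max_retries)) {
      start <- if (is.finite(radius)) {
        repeat {
          s <- stats::runif(3, -radius, radius)
          if (sum(s^2) <= radius^2) break
        }
        centre + s
      } else {
        stats::runif(3, 0, box)
      }
      if (!is.null(all_pos) && nrow(all_pos) > 0) {
        d <- sweep(all_pos, 2, start)
        if (box > 0) d <- d - box * round(d / box)
        if (min(rowSums(d^2)) < min_dist^2) next
      }
      ch <- grow_chain(n_res, r0, start, box, all_pos, min_dist,
                       confine_centre = centre, confine_radius = radius)
      if (!is.null(ch)) {
        all_pos <- rbind(all_pos, ch)
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop(sprintf(
        "chain placement failed for chain %d of %d: box/droplet too small",
        c, n_chains))
    }
  }
  all_pos
}

#' Random dispersed initial configuration
#'
#' Places `config$n_chains` copies of `sequence` as self-avoiding random
#' walks (bond length `params$r0_bond`) in the periodic box, with no
#' nonbonded pair closer than 3 A. Deterministic given `config$seed`.
#'
#' @param sequence a [cg_sequence()].
#' @param config a [sim_config()].
#' @param params a [forcefield_params()].
#' @return a [cg_frame()].
#' @export
initialize_random <- function(sequence, config, params = forcefield_params()) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  pos <- place_chains(sequence, config$n_chains, config$box, params$r0_bond)
  cg_frame(pos, config$box,
           rep(seq_len(config$n_chains), each = sequence$length))
}

#' Pre-assembled droplet initial configuration
#'
#' Packs all chains inside a sphere centred in the box, leaving the rest of
#' the box empty: a condensed starting point that shortens dense-phase
#' equilibration in scaled-down runs.
#'
#' @inheritParams initialize_random
#' @param droplet_radius sphere radius (A); defaults to the radius holding
#'   the chains at a liquid-like bead density of 0.003 / A^3.
#' @return a [cg_frame()].
#' @export
initialize_droplet <- function(sequence, config, params = forcefield_params(),
                               droplet_radius = NULL, droplet_density = 0.002,
                               min_dist = 5) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n_beads <- config$n_chains * sequence$length
  if (is.null(droplet_radius)) droplet_radius <- config$droplet_radius
  if (is.null(droplet_radius)) {
    droplet_radius <- (3 * n_beads / (4 * pi * droplet_density))^(1 / 3)
  }
  centre <- rep(if (config$box > 0) config$box / 2 else 0, 3)
  pos <- place_chains(sequence, config$n_chains, config$box, params$r0_bond,
                      min_dist = min_dist,
                      centre = centre, radius = droplet_radius)
  cg_frame(pos, config$box,
           rep(seq_len(config$n_chains), each = sequence$length))
}

#' Relax a configuration by steepest descent
#'
#' Displacement-capped steepest descent on the total potential energy:
#' removes the steep-core overlaps an initial placement can leave (the
#' 12-10 dispersion core extends to ~6.4 A, well beyond typical packing
#' distances), so dynamics can start from a non-explosive state.
#'
#' @param frame a [cg_frame()].
#' @param sequence the shared [cg_sequence()].
#' @param params a [forcefield_params()].
#' @param n_steps maximum descent steps.
#' @param max_disp largest per-coordinate move per step (A).
#' @param f_tol stop when the largest force component falls below this
#'   (kcal/mol/A).
#' @return the relaxed [cg_frame()].
#' @export
minimize_frame <- function(frame, sequence, params = forcefield_params(),
                           n_steps = 300L, max_disp = 0.2, f_tol = 2) {
  pos <- frame$positions
  for (it in seq_len(n_steps)) {
    fr <- cg_frame(pos, frame$box, frame$chain_index, frame$time)
    f <- forces(fr, sequence, params)
    fmax <- max(abs(f))
    if (fmax < f_tol) break
    step <- f * (max_disp / fmax)
    pos <- pos + step
  }
  cg_frame(pos, frame$box, frame$chain_index, frame$time)
}

#' Run Langevin dynamics
#'
#' Integrates the Langevin equation with the BAOAB splitting at the target
#' temperature, periodic boundaries (minimum image) and Verlet-listed
#' nonbonded forces. Frames are saved every `config$save_every` steps
#' together with the potential-energy breakdown and kinetic temperature.
#' Deterministic given `config$seed`.
#'
#' @param frame starting [cg_frame()] (e.g. from [initialize_random()]).
#' @param sequence the [cg_sequence()] shared by all chains.
#' @param config a [sim_config()].
#' @param params a [forcefield_params()].
#' @return a `cg_trajectory`: list with `positions` (n x 3 x n_frames array,
#'   wrapped into the box), `times`, `box`, `chain_index`, `energy_log`
#'   (per-frame breakdown), `kinetic_T`, and run metadata.
#' @export
run_langevin <- function(frame, sequence, config, params = forcefield_params()) {
  stopifnot(inherits(frame, "cg_frame"))
  if (params$temperature != config$temperature) {
    params$temperature <- config$temperature  # screening follows the run T
  }
  p <- params_for_cpp(params, sequence, frame)
  kBT <- params$kB * config$temperature
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  res <- run_langevin_cpp(frame$positions, frame$box, p,
                          config$dt, config$gamma, kBT, config$mass,
                          config$n_steps, config$save_every, config$skin)
  pos <- res$frames
  if (frame$box > 0) pos <- pos - frame$box * floor(pos / frame$box)
  n <- nrow(frame$positions)
  elog <- res$energy_log
  colnames(elog) <- c("bond", "angle", "dh_intra", "dh_inter",
                      "lj_intra", "lj_inter", "rep_intra", "rep_inter")
  structure(
    list(
      positions = pos, times = res$times, box = frame$box,
      chain_index = frame$chain_index,
      energy_log = elog,
      kinetic_T = 2 * res$kinetic / (3 * n * params$kB),
      velocities = res$velocities,
      sequence = sequence, config = config, params = params,
      seed = config$seed
    ),
    class = "cg_trajectory"
  )
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cg_trajectory> %d frames, %d beads, %d chains, box %.1f A, T = %g K\n",
    n_frames(x), dim(x$positions)[1], length(unique(x$chain_index)),
    x$box, x$config$temperature))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$positions)[3]

#' Extract one frame from a trajectory
#' @param traj a `cg_trajectory`.
#' @param k frame index (1-based).
#' @return a [cg_frame()].
#' @export
get_frame <- function(traj, k) {
  stopifnot(k >= 1, k <= n_frames(traj))
  pos <- matrix(traj$positions[, , k], ncol = 3)
  cg_frame(pos, traj$box, traj$chain_index, traj$times[k])
}

#' Assemble a trajectory from a list of frames
#'
#' Used by the synthetic-data generators and by analysis-only workflows that
#' read bead coordinates from disk.
#'
#' @param frames list of [cg_frame()] with identical bead counts and box.
#' @param times optional numeric time stamps (default frame times).
#' @param sequence,config,params optional metadata.
#' @return a `cg_trajectory`.
#' @export
trajectory_from_frames <- function(frames, times = NULL, sequence = NULL,
                                   config = NULL, params = NULL) {
  n <- nrow(frames[[1]]$positions)
  nf <- length(frames)
  pos <- array(NA_real_, c(n, 3, nf))
  for (k in seq_len(nf)) pos[, , k] <- frames[[k]]$positions
  if (is.null(times)) times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) times <- seq_along(frames) - 1
  structure(
    list(positions = pos, times = times, box = frames[[1]]$box,
         chain_index = frames[[1]]$chain_index,
         energy_log = NULL, kinetic_T = NULL, velocities = NULL,
         sequence = sequence, config = config, params = params,
         seed = if (!is.null(config)) config$seed else NA_integer_),
    class = "cg_trajectory"
  )
}

#' Write / read trajectories as extended XYZ text
#'
#' One block per frame: bead count, a comment line carrying the box, time
#' and chain ids, then `label x y z` rows (labels from the sequence when
#' available, otherwise `X`).
#'
#' @param traj a `cg_trajectory`.
#' @param path output file.
#' @return `write_xyz`: the path, invisibly. `read_xyz`: a `cg_trajectory`.
#' @export
write_xyz <- function(traj, path) {
  n <- dim(traj$positions)[1]
  labels <- if (!is.null(traj$sequence)) {
    rep(traj$sequence$labels, length.out = n)
  } else rep("X", n)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(as.character(n), con)
    writeLines(sprintf('box=%.6f time=%.6f chains="%s"',
                       traj$box, traj$times[k],
                       paste(traj$chain_index, collapse = ",")), con)
    p <- traj$positions[, , k]
    writeLines(sprintf("%s %.6f %.6f %.6f", labels, p[, 1], p[, 2], p[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  i <- 1L
  box <- 0; chain <- NULL
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1L]
    box <- as.numeric(sub('.*box=([0-9.eE+-]+).*', '\\1', hdr))
    tm <- as.numeric(sub('.*time=([0-9.eE+-]+).*', '\\1', hdr))
    ch <- sub('.*chains="([0-9,]+)".*', '\\1', hdr)
    chain <- as.integer(strsplit(ch, ",")[[1]])
    rows <- strsplit(lines[(i + 2L):(i + 1L + n)], "\\s+")
    pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- cg_frame(pos, box, chain, tm)
    times <- c(times, tm)
    i <- i + 2L + n
  }
  trajectory_from_frames(frames, times)
}
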