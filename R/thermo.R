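#' Fit the critical temperature from coexistence densities
#'
#' Fits the order-parameter branch of the coexistence curve,
#' rho_dense - rho_dilute = A (1 - T/Tc)^beta, with the 3D-Ising exponent
#' beta = 0.325 held fixed, by least squares over (A, Tc). A is profiled
#' out analytically for each trial Tc (the model is linear in A), leaving a
#' one-dimensional minimization over Tc > max(T).
#'
#' @param points a data.frame with columns `temperature`, `rho_dense`,
#'   `rho_dilute` (and optionally `weight`), or a list of `phase_point`s
#'   with temperatures filled in.
#' @param beta critical exponent, fixed during the fit (default 0.325).
#' @param weights optional per-point weights (e.g. inverse variances);
#'   defaults to the `weight` column or unweighted.
#' @return a `tc_fit`: list with `Tc`, `A`, `beta`, `residual_norm`,
#'   `weights`, `fitted` and the input `points`.
#' @export
#' @examples
#' pts <- gen_coexistence_curve(Tc_true = 400, A = 1, n_points = 5,
#'                              noise_sd = 0, seed = 1)
#' fit_critical_temperature(pts)$Tc
fit_critical_temperature <- function(points, beta = 0.325, weights = NULL) {
  pts <- as_phase_df(points)
  drho <- pts$rho_dense - pts$rho_dilute
  usable <- drho > 0
  if (sum(usable) < 3) stop("need at least 3 points with rho_dense > rho_dilute")
  if (is.null(weights)) {
    weights <- if ("weight" %in% names(pts)) pts$weight else rep(1, nrow(pts))
  }
  tt <- pts$temperature
  w <- weights
  if (stats::sd(drho) == 0) stop("unfittable curve: order parameter does not decay")
  if (sum(usable) >= 2 &&
      stats::cor(tt[usable], drho[usable], method = "spearman") > 0) {
    stop("unfittable curve: order parameter grows with temperature")
  }
  tmax <- max(tt)
  ssr <- function(Tc) {
    g <- pmax(1 - tt / Tc, 0)^beta
    A <- sum(w * g * drho) / sum(w * g^2)
    sum(w * (drho - A * g)^2)
  }
  # coarse bracket, then high-precision refinement
  grid <- tmax * exp(seq(log(1 + 1e-6), log(20), length.out = 200))
  vals <- vapply(grid, ssr, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(ssr, c(lo, hi), tol = 1e-12)
  # polish once more around the optimum for the noise-free exact-recovery case
  opt2 <- stats::optimize(ssr, c(opt$minimum * (1 - 1e-4), opt$minimum * (1 + 1e-4)),
                          tol = .Machine$double.eps^0.5)
  Tc <- if (opt2$objective < opt$objective) opt2$minimum else opt$minimum
  g <- pmax(1 - tt / Tc, 0)^beta
  A <- sum(w * g * drho) / sum(w * g^2)
  structure(
    list(Tc = Tc, A = A, beta = beta,
         residual_norm = sqrt(sum(w * (drho - A * g)^2)),
         weights = w, fitted = A * g, points = pts),
    class = "tc_fit"
  )
}

#' @export
print.tc_fit <- function(x, ...) {
  cat(sprintf("<tc_fit> Tc = %.4f K, A = %.5g, beta = %.3f, ||r|| = %.3g (%d points)\n",
              x$Tc, x$A, x$beta, x$residual_norm, nrow(x$points)))
  invisible(x)
}

as_phase_df <- function(points) {
  if (is.data.frame(points)) return(points)
  do.call(rbind, lapply(points, function(p) {
    data.frame(temperature = p$temperature, rho_dense = p$rho_dense,
               rho_dilute = p$rho_dilute)
  }))
}

#' Detect a re-entrant density branch
#'
#' A coexistence curve is re-entrant when, with decreasing temperature, the
#' dense-phase density rises, peaks at an interior temperature, and then
#' falls — the signature of highly hydrophobic sequences at low T.
#'
#' @param points data.frame with `temperature` and `rho_dense` columns.
#' @param min_drop minimum relative drop below the peak on both sides
#'   (default 0.05) for the branch to count as re-entrant.
#' @return logical.
#' @export
detect_reentrance <- function(points, min_drop = 0.05) {
  pts <- as_phase_df(points)
  o <- order(pts$temperature, decreasing = TRUE)  # walk with decreasing T
  rho <- pts$rho_dense[o]
  if (length(rho) < 3) return(FALSE)
  k <- which.max(rho)
  if (k == 1 || k == length(rho)) return(FALSE)
  peak <- rho[k]
  rho[length(rho)] < peak * (1 - min_drop) && rho[1] < peak * (1 - min_drop)
}

#' Build a temperature-density phase diagram and fit Tc
#'
#' For each temperature, time-averages the dense and dilute coexistence
#' densities over the post-equilibration portion of the trajectory (block
#' averaging for standard errors, a Kendall trend test on the final half
#' for stationarity), then fits the critical temperature. Points failing
#' the trend test are flagged and excluded from the fit by default.
#'
#' @param trajs named list mapping temperature (names coercible to numeric)
#'   to `cg_trajectory` objects.
#' @param equil_frac initial fraction of frames discarded (default 0.3).
#' @param n_blocks blocks for the standard-error estimate.
#' @param include_unconverged keep trend-test failures in the fit.
#' @param beta critical exponent for the fit.
#' @param min_cluster_chains,cutoff,min_residues condensate-detection
#'   settings, see [phase_densities()] and [chain_contact_graph()].
#' @return list with `points` (data.frame: temperature, rho_dense,
#'   rho_dilute, se_dense, se_dilute, converged), `fit` (a `tc_fit`, or
#'   NULL if unfittable), and `reentrant` (logical flag).
#' @export
build_phase_diagram <- function(trajs, equil_frac = 0.3, n_blocks = 5,
                                include_unconverged = FALSE, beta = 0.325,
                                min_cluster_chains = 3, cutoff = 10,
                                min_residues = 5) {
  temps <- as.numeric(names(trajs))
  stopifnot(!any(is.na(temps)))
  rows <- lapply(seq_along(trajs), function(i) {
    traj <- trajs[[i]]
    nf <- n_frames(traj)
    keep <- seq(from = max(1L, floor(equil_frac * nf) + 1L), to = nf)
    obs <- condensate_observables(traj, cutoff, min_residues,
                                  min_cluster_chains, frames = keep)
    blk <- function(x) {
      bs <- split(x, cut(seq_along(x), breaks = min(n_blocks, length(x)),
                         labels = FALSE))
      m <- vapply(bs, mean, numeric(1))
      stats::sd(m) / sqrt(length(m))
    }
    half <- obs$rho_dense[seq(from = ceiling(nrow(obs) / 2), to = nrow(obs))]
    conv <- TRUE
    if (length(half) >= 5 && stats::sd(half) > 0) {
      kt <- suppressWarnings(
        stats::cor.test(seq_along(half), half, method = "kendall"))
      conv <- !(kt$p.value < 0.05 && abs(kt$estimate) > 0.5)
    }
    data.frame(temperature = temps[i],
               rho_dense = mean(obs$rho_dense),
               rho_dilute = mean(obs$rho_dilute),
               se_dense = blk(obs$rho_dense),
               se_dilute = blk(obs$rho_dilute),
               converged = conv)
  })
  points <- do.call(rbind, rows)
  usable <- points[points$converged | include_unconverged, , drop = FALSE]
  usable$weight <- ifelse(usable$se_dense > 0, 1 / usable$se_dense^2, 1)
  fit <- tryCatch(fit_critical_temperature(usable, beta = beta),
                  error = function(e) {
                    warning("Tc fit failed: ", conditionMessage(e))
                    NULL
                  })
  list(points = points, fit = fit, reentrant = detect_reentrance(points))
}

#' Inter-chain energy profile of the dense phase
#'
#' Per frame, restricts the system to chains of the largest cluster and
#' reports the inter-chain short-range (12-10 dispersion) and long-range
#' (Debye-Hueckel) energies and their sum.
#'
#' @param traj a `cg_trajectory` with sequence metadata.
#' @param params a [forcefield_params()] (default: the trajectory's own).
#' @param frames frame indices (default all).
#' @param per_chain divide energies by the number of cluster chains.
#' @return data.frame with `frame`, `E_short`, `E_long`, `E_total`.
#' @export
interchain_energy_profile <- function(traj, params = NULL, frames = NULL,
                                      per_chain = FALSE) {
  if (is.null(params)) params <- traj$params
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  seqc <- traj$sequence
  rows <- lapply(frames, function(k) {
    fr <- get_frame(traj, k)
    g <- chain_contact_graph(fr)
    cl <- clusters(g)
    chains <- which(cl$membership == cl$largest)
    idx <- fr$chain_index %in% chains
    sub <- cg_frame(fr$positions[idx, , drop = FALSE], fr$box,
                    match(fr$chain_index[idx], chains), fr$time)
    e <- total_energy(sub, seqc, params)
    denom <- if (per_chain) length(chains) else 1
    data.frame(frame = k, E_short = e$lj_inter / denom,
               E_long = e$dh_inter / denom,
               E_total = (e$lj_inter + e$dh_inter) / denom)
  })
  do.call(rbind, rows)
}

#' Radius-of-gyration statistics in droplet or bulk
#'
#' Per-chain Rg from the second moment about the chain centre of mass,
#' sampled over frames. In the `"droplet"` context only chains resident in
#' the largest cluster for the whole analysis window contribute; `"bulk"`
#' uses every chain (the bulk reference is a single isolated chain at
#' matched temperature).
#'
#' @param traj a `cg_trajectory`.
#' @param context `"droplet"` or `"bulk"`.
#' @param equil_frac initial fraction of frames discarded.
#' @param window_frames measurement-window length in frames for the droplet
#'   context: the post-equilibration frames are tiled into windows of this
#'   size, and a chain contributes a window's samples only if it sits in
#'   the largest cluster for that entire window. In a liquid droplet chains
#'   exchange with the surface, so demanding residency over the whole
#'   trajectory would discard everything; per-window residency keeps the
#'   dense-phase restriction while sampling the liquid.
#' @return an `rg_stats`: list with `samples` (per chain x frame Rg values,
#'   A), `mean`, `context` and `temperature`.
#' @export
rg_statistics <- function(traj, context = c("droplet", "bulk"),
                          equil_frac = 0.3, window_frames = 5L) {
  context <- match.arg(context)
  nf <- n_frames(traj)
  keep <- seq(from = max(1L, floor(equil_frac * nf) + 1L), to = nf)
  chains <- sort(unique(traj$chain_index))

  chain_rg <- function(fr, pos, c) {
    p <- pos[fr$chain_index == c, , drop = FALSE]
    com <- colMeans(p)
    sqrt(mean(rowSums(sweep(p, 2, com)^2)))
  }

  samples <- numeric(0)
  if (context == "droplet") {
    windows <- split(keep, (seq_along(keep) - 1L) %/% window_frames)
    for (win in windows) {
      frames <- lapply(win, function(k) get_frame(traj, k))
      resident <- rep(TRUE, length(chains))
      for (fr in frames) {
        cl <- clusters(chain_contact_graph(fr))
        resident <- resident & (cl$membership[chains] == cl$largest)
      }
      if (!any(resident)) next
      for (fr in frames) {
        pos <- unwrap_chains(fr$positions, fr$box, fr$chain_index)
        for (c in chains[resident]) {
          samples <- c(samples, chain_rg(fr, pos, c))
        }
      }
    }
    if (length(samples) == 0) {
      stop("no chain resident in the largest cluster for any full window")
    }
  } else {
    for (k in keep) {
      fr <- get_frame(traj, k)
      pos <- unwrap_chains(fr$positions, fr$box, fr$chain_index)
      for (c in chains) samples <- c(samples, chain_rg(fr, pos, c))
    }
  }
  structure(
    list(samples = samples, mean = mean(samples), context = context,
         temperature = if (!is.null(traj$config)) traj$config$temperature else NA),
    class = "rg_stats"
  )
}
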