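#' Time-continuous chain centre-of-mass series
#'
#' Chain COMs per frame, computed from internally unwrapped chains and made
#' continuous in time by accumulating minimum-image increments between
#' consecutive frames (valid while no chain moves more than half a box
#' between saves).
#'
#' @param traj a `cg_trajectory`.
#' @return array n_chains x 3 x n_frames.
#' @export
chain_com_series <- function(traj) {
  nf <- n_frames(traj)
  chains <- sort(unique(traj$chain_index))
  nc <- length(chains)
  com <- array(NA_real_, c(nc, 3, nf))
  for (k in seq_len(nf)) {
    fr <- get_frame(traj, k)
    pos <- unwrap_chains(fr$positions, fr$box, fr$chain_index)
    for (i in seq_len(nc)) {
      com[i, , k] <- colMeans(pos[fr$chain_index == chains[i], , drop = FALSE])
    }
  }
  if (traj$box > 0) {
    for (k in 2:nf) {
      d <- com[, , k] - com[, , k - 1]
      d <- d - traj$box * round(d / traj$box)
      com[, , k] <- com[, , k - 1] + d
    }
  }
  com
}

residency_matrix <- function(traj, assignments) {
  nf <- n_frames(traj)
  nc <- length(unique(traj$chain_index))
  res <- matrix(FALSE, nf, nc)
  for (k in seq_len(nf)) {
    a <- assignments[[k]]
    res[k, ] <- a$membership == a$largest
  }
  res
}

#' Mean-squared displacement of chain centres of mass
#'
#' Averages squared COM displacements over chains and time origins. When
#' cluster `assignments` are supplied, a chain contributes to a window
#' only if it stays in the largest cluster for the entire window, and the
#' average MSD of the droplet COM over the same windows is subtracted from
#' the chain MSD (removing collective droplet motion).
#'
#' @param traj a `cg_trajectory`.
#' @param assignments optional per-frame [clusters()] results (e.g. from
#'   [cluster_series()]); `NULL` (bulk) uses every chain and no correction.
#' @param max_lag_frac largest lag as a fraction of the trajectory length.
#' @param n_lags number of lag values to evaluate (evenly spaced frames).
#' @param com_correction subtract the droplet-COM MSD (default: on whenever
#'   assignments are given).
#' @return an `msd_curve`: data.frame with `lag` (time units), `msd` (A^2),
#'   `n` (window count per lag) plus attributes `context` and `dt`.
#' @export
msd_chains <- function(traj, assignments = NULL, max_lag_frac = 0.5,
                       n_lags = 100, com_correction = !is.null(assignments)) {
  com <- chain_com_series(traj)
  nf <- dim(com)[3]
  nc <- dim(com)[1]
  dt_frame <- if (nf > 1) diff(traj$times[1:2]) else 1
  max_lag <- max(1L, floor(max_lag_frac * (nf - 1)))
  lag_grid <- unique(round(seq(1, max_lag, length.out = min(n_lags, max_lag))))

  if (!is.null(assignments)) {
    res <- residency_matrix(traj, assignments)
    # run[k, c]: number of consecutive resident frames starting at k
    run <- matrix(0L, nf, nc)
    run[nf, ] <- ifelse(res[nf, ], 1L, 0L)
    if (nf > 1) {
      for (k in (nf - 1):1) run[k, ] <- ifelse(res[k, ], run[k + 1, ] + 1L, 0L)
    }
    drop_com <- matrix(NA_real_, nf, 3)
    for (k in seq_len(nf)) {
      drop_com[k, ] <- colMeans(com[res[k, ], , k, drop = FALSE][, , 1, drop = FALSE])
    }
  }

  msd <- numeric(length(lag_grid))
  nn <- integer(length(lag_grid))
  for (il in seq_along(lag_grid)) {
    L <- lag_grid[il]
    o <- seq_len(nf - L)
    d2 <- (com[, 1, o + L, drop = FALSE] - com[, 1, o, drop = FALSE])^2 +
          (com[, 2, o + L, drop = FALSE] - com[, 2, o, drop = FALSE])^2 +
          (com[, 3, o + L, drop = FALSE] - com[, 3, o, drop = FALSE])^2
    d2 <- matrix(d2, nc, length(o))
    if (!is.null(assignments)) {
      valid <- t(run[o, , drop = FALSE] > L)  # resident over [t0, t0+L]
      nn[il] <- sum(valid)
      if (nn[il] == 0) { msd[il] <- NA_real_; next }
      m_chain <- sum(d2[valid]) / nn[il]
      if (com_correction) {
        dd <- rowSums((drop_com[o + L, , drop = FALSE] -
                         drop_com[o, , drop = FALSE])^2)
        m_chain <- m_chain - mean(dd, na.rm = TRUE)
      }
      msd[il] <- m_chain
    } else {
      nn[il] <- length(d2)
      msd[il] <- mean(d2)
    }
  }
  out <- data.frame(lag = lag_grid * dt_frame, msd = msd, n = nn)
  out <- rbind(data.frame(lag = 0, msd = 0, n = nf * nc), out)
  attr(out, "context") <- if (is.null(assignments)) "bulk" else "droplet"
  attr(out, "dt") <- dt_frame
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' @rdname msd_chains
#' @param ... passed to [msd_chains()].
#' @export
msd_droplet <- function(traj, assignments, ...) {
  curve <- msd_chains(traj, assignments = assignments, ...)
  if (all(is.na(curve$msd[-1]))) {
    warning("no chain resident long enough for any lag; empty MSD curve")
  }
  curve
}

#' Diffusion coefficient from an MSD curve
#'
#' Least-squares slope of MSD versus lag over the fit window, divided by 6
#' (three-dimensional diffusion, MSD = 6 D t).
#'
#' @param curve an `msd_curve` from [msd_chains()].
#' @param fit_window numeric length-2: lag range to fit; default the
#'   5-25% span of the largest usable lag (avoiding the ballistic and
#'   plateau ends).
#' @return a `diffusion_result`: list with `D` (A^2 per time unit), `se`,
#'   `fit_window` and `n_lags`.
#' @export
diffusion_coefficient <- function(curve, fit_window = NULL) {
  usable <- curve[!is.na(curve$msd), , drop = FALSE]
  lmax <- max(usable$lag)
  if (is.null(fit_window)) fit_window <- c(0.05, 0.25) * lmax
  sel <- usable$lag >= fit_window[1] & usable$lag <= fit_window[2]
  if (sum(sel) < 5) stop("fewer than 5 lags inside the fit window")
  fit <- stats::lm(msd ~ lag, data = usable[sel, ])
  co <- summary(fit)$coefficients
  structure(
    list(D = max(0, unname(co["lag", "Estimate"]) / 6),
         se = unname(co["lag", "Std. Error"]) / 6,
         fit_window = fit_window, n_lags = sum(sel)),
    class = "diffusion_result"
  )
}

#' Normalized autocorrelation and 1/e relaxation time
#'
#' The core correlation estimator shared by the inter- and intrachain
#' observables. For a matrix, columns are independent series (chains or
#' pairs) whose correlations are pooled. `demean = TRUE` gives the
#' fluctuation form <dx(0) dx(t)> / <dx^2> (per-column means subtracted);
#' `demean = FALSE` the raw form <x(0) x(t)> / <x(0)^2>. The relaxation
#' time is the 1/e crossing of C(t), linearly interpolated; if C never
#' reaches 1/e within the available lags, `tau` is `NA` and the method tag
#' records `"no-decay"`.
#'
#' @param x numeric vector or matrix (time in rows).
#' @param dt time spacing between rows.
#' @param demean subtract per-column means before correlating.
#' @param max_lag_frac largest lag as a fraction of the series length.
#' @param n_lags number of lag values evaluated.
#' @return a `correlation_result`: list with `lags`, `C`, `tau`, `method`.
#' @export
correlation_time <- function(x, dt = 1, demean = TRUE, max_lag_frac = 0.5,
                             n_lags = 200) {
  x <- as.matrix(x)
  nt <- nrow(x)
  if (demean) x <- sweep(x, 2, colMeans(x))
  denom <- sum(x^2)
  if (denom == 0) stop("zero variance: correlation undefined")
  max_lag <- max(1L, floor(max_lag_frac * (nt - 1)))
  # geometric lag grid: resolves fast decays without wasting work at long lags
  lag_grid <- unique(round(exp(seq(0, log(max_lag),
                                   length.out = min(n_lags, max_lag)))))
  C <- vapply(lag_grid, function(L) {
    num <- sum(x[seq_len(nt - L), , drop = FALSE] *
                 x[seq_len(nt - L) + L, , drop = FALSE])
    den <- sum(x[seq_len(nt - L), , drop = FALSE]^2)
    if (den == 0) return(NA_real_) else num / den
  }, numeric(1))
  lags <- c(0, lag_grid * dt)
  C <- c(1, C)
  thr <- exp(-1)
  below <- which(C < thr)
  if (length(below) == 0) {
    tau <- NA_real_
    method <- "no-decay"
  } else {
    k <- below[1]
    # linear interpolation between the bracketing lags
    tau <- lags[k - 1] + (lags[k] - lags[k - 1]) *
      (C[k - 1] - thr) / (C[k - 1] - C[k])
    method <- "1/e-crossing"
  }
  structure(list(lags = lags, C = C, tau = tau, method = method, dt = dt),
            class = "correlation_result")
}

#' Pairwise contact indicator series
#'
#' For every chain pair that is ever a nearest neighbour, the step function
#' h(t) = 1 while the pair satisfies the contact criterion.
#'
#' @param traj a `cg_trajectory`.
#' @param cutoff,min_residues,symmetric contact criterion,
#'   see [chain_contact_graph()].
#' @return matrix n_frames x n_pairs of 0/1.
#' @export
contact_series <- function(traj, cutoff = 10, min_residues = 5,
                           symmetric = TRUE) {
  nf <- n_frames(traj)
  per_frame <- lapply(seq_len(nf), function(k) {
    g <- chain_contact_graph(get_frame(traj, k), cutoff, min_residues,
                             symmetric)
    if (nrow(g$edges) == 0) return(character(0))
    paste(pmin(g$edges[, 1], g$edges[, 2]),
          pmax(g$edges[, 1], g$edges[, 2]), sep = "-")
  })
  all_pairs <- unique(unlist(per_frame))
  h <- matrix(0L, nf, length(all_pairs),
              dimnames = list(NULL, all_pairs))
  for (k in seq_len(nf)) h[k, per_frame[[k]]] <- 1L
  h
}

#' Interchain neighbour-exchange relaxation time
#'
#' Autocorrelation of the pairwise nearest-neighbour indicator h(t),
#' averaged over pairs and time origins with h = 1 at the origin, so C(t)
#' is the probability that a contact present at time 0 is present at time
#' t. The relaxation time is the 1/e crossing; frozen contact sets return
#' the no-decay sentinel.
#'
#' @inheritParams contact_series
#' @param demean use the mean-subtracted (fluctuation) correlation instead
#'   of the raw indicator form.
#' @param max_lag_frac,n_lags lag grid, see [correlation_time()].
#' @return a `correlation_result` (see [correlation_time()]).
#' @export
interchain_exchange_time <- function(traj, cutoff = 10, min_residues = 5,
                                     demean = FALSE, max_lag_frac = 0.5,
                                     n_lags = 200) {
  h <- contact_series(traj, cutoff, min_residues)
  if (ncol(h) == 0) stop("no chain pair ever satisfies the contact criterion")
  dt_frame <- if (n_frames(traj) > 1) diff(traj$times[1:2]) else 1
  correlation_time(h, dt = dt_frame, demean = demean,
                   max_lag_frac = max_lag_frac, n_lags = n_lags)
}

#' Per-chain end-to-end distance series
#'
#' @param traj a `cg_trajectory`.
#' @return matrix n_frames x n_chains of end-to-end distances (A).
#' @export
end_to_end_series <- function(traj) {
  nf <- n_frames(traj)
  chains <- sort(unique(traj$chain_index))
  d <- matrix(NA_real_, nf, length(chains))
  for (k in seq_len(nf)) {
    fr <- get_frame(traj, k)
    pos <- unwrap_chains(fr$positions, fr$box, fr$chain_index)
    for (i in seq_along(chains)) {
      idx <- which(fr$chain_index == chains[i])
      d[k, i] <- sqrt(sum((pos[idx[length(idx)], ] - pos[idx[1], ])^2))
    }
  }
  d
}

#' Intrachain end-to-end relaxation time
#'
#' Fluctuation autocorrelation of the end-to-end distance,
#' <dd(0) dd(t)> / <dd^2>, averaged over chains; relaxation time from the
#' 1/e crossing. In the `"droplet"` context only chains resident in the
#' largest cluster for the whole trajectory contribute.
#'
#' @param traj a `cg_trajectory`.
#' @param context `"droplet"` or `"bulk"`.
#' @param demean fluctuation (default) vs raw correlation.
#' @param max_lag_frac,n_lags lag grid, see [correlation_time()].
#' @return a `correlation_result`.
#' @export
intrachain_relaxation_time <- function(traj, context = c("bulk", "droplet"),
                                       demean = TRUE, max_lag_frac = 0.5,
                                       n_lags = 200) {
  context <- match.arg(context)
  d <- end_to_end_series(traj)
  if (context == "droplet") {
    ass <- cluster_series(traj)
    res <- residency_matrix(traj, ass)
    keep <- apply(res, 2, all)
    if (!any(keep)) stop("no chain resident in the largest cluster throughout")
    d <- d[, keep, drop = FALSE]
  }
  if (all(apply(d, 2, stats::sd) == 0)) {
    stop("zero variance: end-to-end distance is constant")
  }
  dt_frame <- if (n_frames(traj) > 1) diff(traj$times[1:2]) else 1
  correlation_time(d, dt = dt_frame, demean = demean,
                   max_lag_frac = max_lag_frac, n_lags = n_lags)
}
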