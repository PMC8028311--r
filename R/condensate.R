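#' Chain contact graph
#'
#' Two chains are nearest neighbours when at least `min_residues` residues
#' of each lie within `cutoff` of some residue of the other (the symmetric
#' reading of the contact criterion; `symmetric = FALSE` switches to the
#' laxer rule of at least `min_residues` inter-chain residue pairs within
#' the cutoff). Periodic images are honoured.
#'
#' @param frame a [cg_frame()].
#' @param cutoff contact distance (A), default 10.
#' @param min_residues minimum residue count per chain, default 5.
#' @param symmetric logical, see above.
#' @return a `contact_graph`: list with `n_chains`, `edges` (two-column
#'   matrix of chain indices, 1-based) and the per-pair contact `counts`.
#' @export
chain_contact_graph <- function(frame, cutoff = 10, min_residues = 5,
                                symmetric = TRUE) {
  stopifnot(inherits(frame, "cg_frame"))
  cc <- contact_counts_cpp(frame$positions, frame$box,
                           frame$chain_index - 1L, cutoff)
  keep <- if (symmetric) {
    cc[, "n_res_a"] >= min_residues & cc[, "n_res_b"] >= min_residues
  } else {
    cc[, "n_pairs"] >= min_residues
  }
  edges <- cbind(cc[keep, "a", drop = TRUE], cc[keep, "b", drop = TRUE]) + 1L
  if (length(edges) == 0) edges <- matrix(integer(0), 0, 2)
  structure(
    list(n_chains = length(unique(frame$chain_index)),
         edges = edges, counts = cc),
    class = "contact_graph"
  )
}

#' Connected components of a contact graph
#'
#' Chains belonging to one connected component form one cluster; the
#' largest component is the condensate. Ties on size break to the lowest
#' cluster label.
#'
#' @param graph a `contact_graph` (or a list with `n_chains` and `edges`).
#' @return a `cluster_assignment`: list with `membership` (cluster label per
#'   chain), `sizes` (chains per cluster) and `largest` (label of the
#'   largest cluster).
#' @export
clusters <- function(graph) {
  n <- graph$n_chains
  adj <- vector("list", n)
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    a <- e[k, 1]; b <- e[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  membership <- integer(n)
  lab <- 0L
  for (s in seq_len(n)) {
    if (membership[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    membership[s] <- lab
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (membership[w] == 0L) {
          membership[w] <- lab
          queue <- c(queue, w)
        }
      }
    }
  }
  sizes <- tabulate(membership, nbins = lab)
  structure(
    list(membership = membership, sizes = sizes,
         largest = which.max(sizes)),  # which.max takes the lowest label on ties
    class = "cluster_assignment"
  )
}

# --- periodic unwrapping ----------------------------------------------------

# unwrap each chain internally: walk the chain accumulating minimum-image
# bond vectors
unwrap_chains <- function(pos, box, chain_index) {
  if (box <= 0) return(pos)
  out <- pos
  for (c in unique(chain_index)) {
    idx <- which(chain_index == c)
    if (length(idx) < 2) next
    d <- diff(pos[idx, , drop = FALSE])
    d <- d - box * round(d / box)
    cum <- matrix(apply(d, 2, cumsum), ncol = 3)
    out[idx[-1], ] <- sweep(cum, 2, pos[idx[1], ], FUN = "+")
  }
  out
}

# unwrap a cluster of chains: chains already internally unwrapped; shift each
# chain by whole box vectors so its centre of mass sits minimum-image close
# to the chain it was reached from (BFS over contact edges)
unwrap_cluster <- function(pos, box, chain_index, cluster_chains, edges) {
  if (box <= 0) return(pos)
  pos <- unwrap_chains(pos, box, chain_index)
  coms <- t(vapply(cluster_chains, function(c) {
    colMeans(pos[chain_index == c, , drop = FALSE])
  }, numeric(3)))
  rownames(coms) <- cluster_chains
  adj <- lapply(cluster_chains, function(c) {
    nb <- c(edges[edges[, 1] == c, 2], edges[edges[, 2] == c, 1])
    intersect(nb, cluster_chains)
  })
  names(adj) <- cluster_chains
  visited <- setNames(rep(FALSE, length(cluster_chains)),
                      as.character(cluster_chains))
  shift <- matrix(0, length(cluster_chains), 3,
                  dimnames = list(as.character(cluster_chains), NULL))
  root <- as.character(cluster_chains[1])
  visited[root] <- TRUE
  queue <- cluster_chains[1]
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    vkey <- as.character(v)
    for (w in adj[[vkey]]) {
      wkey <- as.character(w)
      if (visited[wkey]) next
      # shift w by whole box vectors so it lands minimum-image close to v
      d <- coms[wkey, ] - (coms[vkey, ] + shift[vkey, ])
      shift[wkey, ] <- -box * round(d / box)
      visited[wkey] <- TRUE
      queue <- c(queue, w)
    }
  }
  for (c in cluster_chains) {
    ckey <- as.character(c)
    idx <- chain_index == c
    pos[idx, ] <- sweep(pos[idx, , drop = FALSE], 2, shift[ckey, ], FUN = "+")
  }
  pos
}

largest_cluster_coords <- function(frame, assignment, graph = NULL) {
  cl_chains <- which(assignment$membership == assignment$largest)
  edges <- if (!is.null(graph)) graph$edges else matrix(integer(0), 0, 2)
  pos <- unwrap_cluster(frame$positions, frame$box, frame$chain_index,
                        cl_chains, edges)
  pos[frame$chain_index %in% cl_chains, , drop = FALSE]
}

# --- convex hull volume -----------------------------------------------------

#' Volume of the 3D convex hull of a point set
#'
#' Incremental (beneath-beyond) convex hull; returns `NA` for degenerate
#' (collinear/coplanar) inputs, for which callers fall back to a
#' bounding-box volume.
#'
#' @param points n x 3 matrix.
#' @return hull volume, or `NA_real_` if the points are degenerate.
#' @export
convex_hull_volume <- function(points) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 4) return(NA_real_)
  scale <- max(apply(pts, 2, function(x) diff(range(x))), 1e-12)
  eps <- 1e-9 * scale

  # initial simplex from extreme points
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] < eps^2) return(NA_real_)
  u <- pts[i2, ] - pts[i1, ]; u <- u / sqrt(sum(u^2))
  rel <- sweep(pts, 2, pts[i1, ])
  perp <- rel - outer(drop(rel %*% u), u)
  d2 <- rowSums(perp^2)
  i3 <- which.max(d2)
  if (d2[i3] < eps^2) return(NA_real_)
  nrm <- pracma_cross(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  d3 <- abs(drop(rel %*% nrm)) / sqrt(sum(nrm^2))
  i4 <- which.max(d3)
  if (d3[i4] < eps) return(NA_real_)

  verts <- c(i1, i2, i3, i4)
  interior <- colMeans(pts[verts, ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    a <- pts[f[1], ]; b <- pts[f[2], ]; c <- pts[f[3], ]
    nn <- pracma_cross(b - a, c - a)
    if (sum(nn * (interior - a)) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))

  face_geom <- function(faces) {
    a <- pts[faces[, 1], , drop = FALSE]
    b <- pts[faces[, 2], , drop = FALSE]
    c <- pts[faces[, 3], , drop = FALSE]
    e1 <- b - a; e2 <- c - a
    nn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    list(normal = nn, a = a)
  }

  rest <- setdiff(seq_len(n), verts)
  for (p in rest) {
    g <- face_geom(faces)
    sd <- rowSums(g$normal * (matrix(pts[p, ], nrow(faces), 3, byrow = TRUE) - g$a))
    nl <- sqrt(rowSums(g$normal^2))
    visible <- sd > eps * nl
    if (!any(visible)) next
    vis_faces <- faces[visible, , drop = FALSE]
    # horizon = edges used exactly once among visible faces
    ed <- rbind(vis_faces[, c(1, 2)], vis_faces[, c(2, 3)], vis_faces[, c(3, 1)])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    once <- names(which(table(key) == 1))
    horizon <- ed[key %in% once, , drop = FALSE]
    faces <- faces[!visible, , drop = FALSE]
    new_faces <- cbind(p, horizon)
    new_faces <- t(apply(new_faces, 1, orient))
    faces <- rbind(faces, new_faces)
  }

  g <- face_geom(faces)
  # signed volume with outward normals, apex at the interior point
  v <- sum(rowSums(g$normal * sweep(g$a, 2, interior))) / 6
  abs(v)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Coexistence densities of a frame
#'
#' The dense-phase density is the bead count of the largest cluster divided
#' by the volume of its convex hull (computed after periodic unwrapping;
#' bounding box if the hull is degenerate). Chains in clusters smaller than
#' `min_cluster_chains` count as dilute, with the dilute volume equal to
#' the box volume minus the hull volume. Intermediate oligomers are
#' reported separately so bead bookkeeping stays exact.
#'
#' @param frame a [cg_frame()] with a periodic box.
#' @param assignment a [clusters()] result for this frame.
#' @param min_cluster_chains clusters below this chain count are dilute
#'   (default 3).
#' @param graph the `contact_graph` used for `assignment` (needed for
#'   unwrapping; recomputed if omitted).
#' @return a `phase_point`: list with `rho_dense`, `rho_dilute` (beads/A^3),
#'   `n_dense`, `n_dilute`, `n_intermediate`, `hull_volume`,
#'   `largest_size` and `temperature` (NA here; filled by
#'   [build_phase_diagram()]).
#' @export
phase_densities <- function(frame, assignment, min_cluster_chains = 3,
                            graph = NULL) {
  stopifnot(frame$box > 0)
  if (is.null(graph)) graph <- chain_contact_graph(frame)
  memb <- assignment$membership
  chains_per_bead <- frame$chain_index
  dense_chains <- which(memb == assignment$largest)
  dilute_chains <- which(assignment$sizes[memb] < min_cluster_chains)
  dilute_chains <- setdiff(dilute_chains, dense_chains)
  inter_chains <- setdiff(seq_along(memb), c(dense_chains, dilute_chains))

  coords <- largest_cluster_coords(frame, assignment, graph)
  vol <- convex_hull_volume(coords)
  if (is.na(vol)) {
    warning("degenerate hull for the largest cluster; using bounding box")
    ext <- apply(coords, 2, function(x) diff(range(x)))
    vol <- prod(pmax(ext, 1e-6))
  }
  vbox <- frame$box^3
  n_dense <- sum(chains_per_bead %in% dense_chains)
  n_dilute <- sum(chains_per_bead %in% dilute_chains)
  n_inter <- sum(chains_per_bead %in% inter_chains)
  structure(
    list(
      temperature = NA_real_,
      rho_dense = n_dense / vol,
      rho_dilute = n_dilute / max(vbox - vol, 1e-9),
      n_dense = n_dense, n_dilute = n_dilute, n_intermediate = n_inter,
      hull_volume = vol, largest_size = assignment$sizes[assignment$largest]
    ),
    class = "phase_point"
  )
}

#' Shape anisotropy of the largest cluster
#'
#' With d_x, d_y, d_z the largest axis-aligned diameters of the (unwrapped)
#' largest cluster, returns d_x/d_y + d_y/d_z + d_z/d_x. A sphere gives 3;
#' any unequal diameters give a value above 3 (AM-GM on three ratios whose
#' product is 1).
#'
#' @inheritParams phase_densities
#' @return numeric anisotropy >= 3.
#' @export
shape_anisotropy <- function(frame, assignment, graph = NULL) {
  if (is.null(graph)) graph <- chain_contact_graph(frame)
  coords <- largest_cluster_coords(frame, assignment, graph)
  if (nrow(coords) < 4) stop("shape undefined: largest cluster has < 4 beads")
  d <- unname(apply(coords, 2, function(x) diff(range(x))))
  if (any(d <= 0)) stop("shape undefined: zero extent along an axis")
  d[1] / d[2] + d[2] / d[3] + d[3] / d[1]
}

#' Per-frame condensate observables of a trajectory
#'
#' Runs contact-graph clustering on every frame and tabulates densities,
#' largest-cluster size and shape anisotropy.
#'
#' @param traj a `cg_trajectory`.
#' @param cutoff,min_residues contact criterion, see [chain_contact_graph()].
#' @param min_cluster_chains dilute-phase threshold, see [phase_densities()].
#' @param frames integer indices of frames to analyse (default all).
#' @return data.frame with one row per analysed frame: `frame`, `time`,
#'   `rho_dense`, `rho_dilute`, `largest_size`, `anisotropy`.
#' @export
condensate_observables <- function(traj, cutoff = 10, min_residues = 5,
                                   min_cluster_chains = 3, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  rows <- lapply(frames, function(k) {
    fr <- get_frame(traj, k)
    g <- chain_contact_graph(fr, cutoff, min_residues)
    cl <- clusters(g)
    pp <- phase_densities(fr, cl, min_cluster_chains, graph = g)
    an <- tryCatch(shape_anisotropy(fr, cl, graph = g),
                   error = function(e) NA_real_)
    data.frame(frame = k, time = traj$times[k],
               rho_dense = pp$rho_dense, rho_dilute = pp$rho_dilute,
               largest_size = pp$largest_size, anisotropy = an)
  })
  do.call(rbind, rows)
}

#' Per-frame cluster assignments of a trajectory
#'
#' @inheritParams condensate_observables
#' @return list of [clusters()] results, one per frame.
#' @export
cluster_series <- function(traj, cutoff = 10, min_residues = 5) {
  lapply(seq_len(n_frames(traj)), function(k) {
    clusters(chain_contact_graph(get_frame(traj, k), cutoff, min_residues))
  })
}
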