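test_that("contact criterion: overlapping, borderline and distant chains", {
  # two 6-bead chains exactly on top of each other -> edge
  pos <- rbind(cbind(1:6 * 3.8, 0, 0), cbind(1:6 * 3.8, 0.5, 0))
  fr <- cg_frame(pos, 200, rep(1:2, each = 6))
  g <- chain_contact_graph(fr, cutoff = 10, min_residues = 5)
  expect_equal(nrow(g$edges), 1)
  # exactly 5 residues of each within 10 A -> edge; only 4 -> none
  mk <- function(n_close) {
    a <- cbind(1:6 * 3.8, 0, 0)
    b <- cbind(1:6 * 3.8, 9, 0)
    if (n_close < 6) b[(n_close + 1):6, 2] <- 100  # push the rest far away
    cg_frame(rbind(a, b), 400, rep(1:2, each = 6))
  }
  expect_equal(nrow(chain_contact_graph(mk(5))$edges), 1)
  expect_equal(nrow(chain_contact_graph(mk(4))$edges), 0)
  # all chains far apart -> empty edge set
  far <- cg_frame(rbind(cbind(1:6 * 3.8, 0, 0), cbind(1:6 * 3.8, 150, 0),
                        cbind(1:6 * 3.8, 0, 150)), 400, rep(1:3, each = 6))
  expect_equal(nrow(chain_contact_graph(far)$edges), 0)
})

test_that("contacts honour periodic images", {
  # chains near opposite faces of the box are neighbours through the wall
  a <- cbind(1:6 * 3.8, 1, 50)
  b <- cbind(1:6 * 3.8, 199, 50)
  fr <- cg_frame(rbind(a, b), 200, rep(1:2, each = 6))
  expect_equal(nrow(chain_contact_graph(fr)$edges), 1)
})

test_that("components match igraph and brute-force reachability on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    m <- sample(0:(n * 2), 1)
    edges <- if (m > 0) {
      cbind(sample.int(n, m, replace = TRUE), sample.int(n, m, replace = TRUE))
    } else matrix(integer(0), 0, 2)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    cl <- clusters(list(n_chains = n, edges = edges))
    # brute force
    bf <- components_bruteforce(n, edges)
    expect_equal(length(unique(cl$membership)), length(unique(bf)))
    same_bf <- outer(bf, bf, "==")
    same_cl <- outer(cl$membership, cl$membership, "==")
    expect_identical(same_cl, same_bf)
    # igraph cross-check
    ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    expect_equal(sort(cl$sizes, decreasing = TRUE),
                 sort(unname(igraph::components(ig)$csize), decreasing = TRUE))
  }
})

test_that("degenerate component cases: empty and complete graphs", {
  n <- 9
  cl0 <- clusters(list(n_chains = n, edges = matrix(integer(0), 0, 2)))
  expect_equal(cl0$sizes, rep(1L, n))
  full <- t(utils::combn(n, 2))
  cl1 <- clusters(list(n_chains = n, edges = full))
  expect_equal(cl1$sizes, n)
  expect_equal(cl1$largest, 1L)
})

test_that("convex hull volume matches closed forms", {
  # unit cube corners (+ interior points that must not change the hull)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 10
  expect_equal(convex_hull_volume(cube), 1000, tolerance = 1e-9)
  set.seed(3)
  inner <- matrix(runif(300, 0.5, 9.5), ncol = 3)
  expect_equal(convex_hull_volume(rbind(cube, inner)), 1000, tolerance = 1e-9)
  # tetrahedron with volume 1/6 * a^3
  tet <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  expect_equal(convex_hull_volume(tet), 8 / 6, tolerance = 1e-9)
  # dense sampling of a ball approaches its volume from below
  set.seed(4)
  u <- matrix(rnorm(3 * 4000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * (runif(4000)^(1 / 3)) * 30
  vol <- convex_hull_volume(u)
  expect_lt(vol, 4 / 3 * pi * 30^3)
  expect_gt(vol, 0.9 * 4 / 3 * pi * 30^3)
  # degenerate input
  expect_true(is.na(convex_hull_volume(cbind(1:10, 2 * (1:10), 3 * (1:10)))))
})

test_that("phase densities recover planted droplet + gas geometry within 10%", {
  fr <- gen_droplet_config(n_dense_chains = 60, n_gas_chains = 25,
                           chain_length = 20, droplet_axes = c(55, 55, 55),
                           box = 300, seed = 5)
  gt <- attr(fr, "ground_truth")
  g <- chain_contact_graph(fr)
  cl <- clusters(g)
  pp <- phase_densities(fr, cl, graph = g)
  expect_equal(pp$rho_dense, gt$rho_dense, tolerance = 0.10)
  expect_equal(pp$rho_dilute, gt$rho_dilute, tolerance = 0.10)
})

test_that("bead bookkeeping is exact across phases", {
  fr <- gen_droplet_config(40, 15, 10, c(45, 45, 45), 250, seed = 6)
  g <- chain_contact_graph(fr)
  cl <- clusters(g)
  pp <- phase_densities(fr, cl, graph = g)
  expect_equal(pp$n_dense + pp$n_dilute + pp$n_intermediate,
               nrow(fr$positions))
})

test_that("all chains in one compact droplet give zero dilute density", {
  fr <- gen_droplet_config(30, 0, 15, c(28, 28, 28), 300, seed = 7)
  g <- chain_contact_graph(fr, min_residues = 1)
  cl <- clusters(g)
  expect_equal(max(cl$sizes), 30)
  pp <- phase_densities(fr, cl, graph = g)
  expect_equal(pp$rho_dilute, 0)
})

test_that("shape anisotropy: sphere gives 3, planted ellipsoids the cyclic sum", {
  fr <- gen_droplet_config(1, 0, 3000, c(60, 60, 60), 300, seed = 8)
  cl <- list(membership = 1L, sizes = 1L, largest = 1L)
  expect_equal(shape_anisotropy(fr, cl), 3, tolerance = 0.05)
  # exact cube corners: d_x = d_y = d_z exactly -> exactly 3
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 20 + 100
  frc <- cg_frame(cube, 300, rep(1L, 8))
  expect_identical(shape_anisotropy(frc, cl), 3)
  # 2:1:1 ellipsoid -> 2/1 + 1/1 + 1/2 = 3.5
  fre <- gen_droplet_config(1, 0, 4000, c(60, 30, 30), 300, seed = 9)
  expect_equal(shape_anisotropy(fre, cl), 3.5, tolerance = 0.06)
  expect_error(shape_anisotropy(
    cg_frame(matrix(1:9, 3, 3), 100, rep(1L, 3)), cl), "undefined")
})

test_that("anisotropy is at least 3 for arbitrary clusters (AM-GM)", {
  set.seed(10)
  cl <- list(membership = 1L, sizes = 1L, largest = 1L)
  for (rep in 1:25) {
    pts <- matrix(rnorm(3 * 40, sd = runif(1, 2, 30)), ncol = 3) + 100
    fr <- cg_frame(pts, 300, rep(1L, 40))
    expect_gte(shape_anisotropy(fr, cl), 3)
  }
})

test_that("contact graph and clusters are invariant under rigid motion", {
  fr <- gen_droplet_config(12, 6, 8, c(40, 40, 40), 250, seed = 11)
  g1 <- chain_contact_graph(fr)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ctr <- rep(125, 3)
  pos2 <- sweep(sweep(fr$positions, 2, ctr) %*% R, 2, ctr, FUN = "+")
  g2 <- chain_contact_graph(cg_frame(pos2, fr$box, fr$chain_index))
  norm_edges <- function(g) {
    e <- cbind(pmin(g$edges[, 1], g$edges[, 2]),
               pmax(g$edges[, 1], g$edges[, 2]))
    e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  expect_identical(norm_edges(g1), norm_edges(g2))
  expect_identical(clusters(g1)$sizes, clusters(g2)$sizes)
})

test_that("cluster unwrapping reconnects a droplet split across the boundary", {
  # droplet centred on a box corner: beads wrap to 8 octants
  box <- 200
  fr <- gen_droplet_config(20, 0, 10, c(26, 26, 26), box, seed = 12)
  shift <- fr$positions + (box / 2)   # move centre to the corner
  wrapped <- shift - box * floor(shift / box)
  frw <- cg_frame(wrapped, box, fr$chain_index)
  g <- chain_contact_graph(frw, min_residues = 2)
  cl <- clusters(g)
  expect_equal(max(cl$sizes), 20)
  an <- shape_anisotropy(frw, cl, graph = g)
  expect_lt(an, 3.6)  # reconnected droplet is still roughly spherical
  pp <- phase_densities(frw, cl, graph = g)
  gt <- attr(fr, "ground_truth")
  expect_equal(pp$rho_dense, gt$rho_dense, tolerance = 0.2)
})
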