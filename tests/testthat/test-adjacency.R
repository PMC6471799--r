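test_that("edge rule matches a brute-force all-pairs check", {
  set.seed(51)
  for (rep in 1:5) {
    conf <- random_conf_matrix(50)
    theta <- runif(1, 0.5, 1.5)
    g <- build_adjacency_graph(conf, theta = theta, xi = 0.35)
    ref <- oracle_edges(conf, theta, 0.35)
    expect_equal(matrix(as.numeric(g$edges[, 1:2]), ncol = 2),
                 matrix(as.numeric(ref), ncol = 2))
    # edge weights are the full angular RMSD
    for (r in seq_len(min(nrow(g$edges), 10)))
      expect_equal(unname(g$edges[r, 3]),
                   angular_rmsd(conf[g$edges[r, 1], ], conf[g$edges[r, 2], ]))
  }
})

test_that("limit cases: single vertex and effectively infinite theta", {
  g1 <- build_adjacency_graph(random_conf_matrix(1), theta = 0.5)
  expect_equal(g1$n, 1)
  expect_equal(nrow(g1$edges), 0)
  conf <- random_conf_matrix(12)
  g2 <- build_adjacency_graph(conf, theta = 1e6)
  expect_equal(nrow(g2$edges), choose(12, 2)) # complete graph
})

test_that("tune_theta returns the smallest connecting grid value", {
  # two conformations at a known central distance: the returned theta must
  # be the first grid point strictly above it
  a <- tripeptide_conformation(c(0, 0, 0), c(0, 0, 0))
  b <- tripeptide_conformation(c(0, 0.9, 0), c(0, 0.9, 0))
  conf <- rbind(a, b)
  dc <- central_distance(a, b)
  th <- tune_theta(conf, xi = 2, grid_step = 0.05)
  expect_gt(th, dc)
  expect_lte(th - 0.05, dc)
  # multi-cluster fixture: theta connects, theta - step does not
  set.seed(52)
  centers <- c(-2, 0, 2)
  conf <- do.call(rbind, lapply(centers, function(cc)
    t(vapply(1:8, function(i)
      tripeptide_conformation(rnorm(3, cc, 0.05), rnorm(3, cc, 0.05)),
      numeric(6)))))
  th <- tune_theta(conf, xi = 0.35, grid_step = 0.05)
  n_comp <- function(theta) {
    g <- build_adjacency_graph(conf, theta, xi = 0.35)
    ig <- igraph::make_empty_graph(g$n, directed = FALSE)
    if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges[, 1:2]))
    igraph::components(ig)$no
  }
  expect_equal(n_comp(th), 1)
  expect_gt(n_comp(th - 0.05), 1)
  # degenerate singleton library: trivially connected at the first grid value
  expect_equal(tune_theta(random_conf_matrix(1), grid_step = 0.05), 0.05)
  # determinism
  expect_identical(th, tune_theta(conf, xi = 0.35, grid_step = 0.05))
})

test_that("density counts graph neighbours within zeta, plus one", {
  # constructed: vertex 1 has 3 neighbours at d < zeta, one farther
  base <- tripeptide_conformation(rep(0, 3), rep(0, 3))
  near <- lapply(c(0.05, 0.08, 0.1), function(e)
    tripeptide_conformation(c(e, 0, 0), rep(0, 3)))
  far <- tripeptide_conformation(c(0.5, 0, 0), rep(0, 3))
  conf <- do.call(rbind, c(list(base), near, list(far)))
  g <- build_adjacency_graph(conf, theta = 1, xi = 0.35)
  rho <- compute_density(g, zeta = 0.2)
  expect_equal(rho[1], 4L)
  # isolated vertex has density 1
  g1 <- build_adjacency_graph(random_conf_matrix(1), theta = 0.5)
  expect_equal(compute_density(g1, zeta = 0.2), 1L)
  expect_error(compute_density(g, zeta = 1.5), "smaller than theta")
})

test_that("density and heuristic match independent recomputations", {
  set.seed(53)
  for (rep in 1:5) {
    conf <- random_conf_matrix(40)
    g <- build_adjacency_graph(conf, theta = runif(1, 0.8, 1.4), xi = 0.35)
    expect_identical(compute_density(g, zeta = 0.2), oracle_density(g, 0.2))
    goal <- sample.int(g$n, 1)
    h <- precompute_goal_heuristic(g, goal)
    expect_equal(h[goal], 0)
    expect_equal(h, oracle_shortest_paths(g, goal), tolerance = 1e-12)
  }
})

test_that("heuristic sums hand-checkable path weights", {
  # vertices along phi1 only: d(1,2) = 0.3, d(2,3) = 0.4, d(1,3) = 0.7;
  # all central distances are 0, so theta = 0.5 with xi = 0 prunes the
  # direct 1-3 edge and leaves the path graph 1-2-3
  conf <- rbind(
    tripeptide_conformation(c(0.0, 0, 0), c(0, 0, 0)),
    tripeptide_conformation(c(0.3 * sqrt(6), 0, 0), c(0, 0, 0)),
    tripeptide_conformation(c(0.7 * sqrt(6), 0, 0), c(0, 0, 0)))
  expect_equal(angular_rmsd(conf[1, ], conf[2, ]), 0.3, tolerance = 1e-12)
  expect_equal(angular_rmsd(conf[2, ], conf[3, ]), 0.4, tolerance = 1e-12)
  g <- build_adjacency_graph(conf, theta = 0.5, xi = 0)
  expect_equal(nrow(g$edges), 2)
  h <- precompute_goal_heuristic(g, 3)
  expect_equal(h, c(0.7, 0.4, 0), tolerance = 1e-12)
  # unreachable vertices carry an Inf sentinel
  g_iso <- build_adjacency_graph(rbind(conf, tripeptide_conformation(
    c(-3, 0, 0), c(3, 0, 0))), theta = 0.5, xi = 0)
  expect_equal(precompute_goal_heuristic(g_iso, 3)[4], Inf)
})

test_that("density is invariant under vertex relabelling", {
  set.seed(54)
  conf <- random_conf_matrix(30)
  g <- build_adjacency_graph(conf, theta = 1.0, xi = 0.35)
  rho <- compute_density(g, 0.2)
  perm <- sample(30)
  g2 <- build_adjacency_graph(conf[perm, ], theta = 1.0, xi = 0.35)
  rho2 <- compute_density(g2, 0.2)
  expect_identical(rho2, rho[perm])
})
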