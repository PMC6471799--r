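# Independent oracle implementations and fixture builders shared by the
# suite. Oracles deliberately use different constructions than the package
# code paths they check.

# torsion via the normal-vector atan2 construction
oracle_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  b2u <- b2 / sqrt(sum(b2^2))
  atan2(sum(cr(n1, n2) * b2u), sum(n1 * n2))
}

# single-source shortest paths by plain Bellman-Ford edge relaxation
oracle_shortest_paths <- function(graph, goal) {
  n <- graph$n
  dist <- rep(Inf, n)
  dist[goal] <- 0
  e <- graph$edges
  for (pass in seq_len(n)) {
    changed <- FALSE
    for (r in seq_len(nrow(e))) {
      u <- e[r, 1]; v <- e[r, 2]; d <- e[r, 3]
      if (dist[u] + d < dist[v]) { dist[v] <- dist[u] + d; changed <- TRUE }
      if (dist[v] + d < dist[u]) { dist[u] <- dist[v] + d; changed <- TRUE }
    }
    if (!changed) break
  }
  dist
}

# edge set by direct per-pair evaluation of the two metrics
oracle_edges <- function(conf, theta, xi) {
  n <- nrow(conf)
  out <- NULL
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    if (central_distance(conf[u, ], conf[v, ]) < theta &&
        angular_rmsd(conf[u, ], conf[v, ]) < theta + xi)
      out <- rbind(out, c(u, v))
  }
  if (is.null(out)) matrix(0L, 0, 2) else out
}

# densities by direct recount over the edge list
oracle_density <- function(graph, zeta) {
  rho <- rep(1L, graph$n)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    if (e[r, 3] < zeta) {
      rho[e[r, 1]] <- rho[e[r, 1]] + 1L
      rho[e[r, 2]] <- rho[e[r, 2]] + 1L
    }
  }
  rho
}

# random conformation vector / matrix
random_conf <- function() {
  tripeptide_conformation(stats::runif(3, -pi, pi), stats::runif(3, -pi, pi))
}
random_conf_matrix <- function(n) {
  t(vapply(seq_len(n), function(i) random_conf(), numeric(6)))
}

# database with `counts[i]` dummy conformations for each key (angles spread
# on a tight grid so libraries index cleanly)
make_counts_db <- function(keys, counts) {
  recs <- do.call(rbind, lapply(seq_along(keys), function(i)
    data.frame(key = keys[i],
               phi1 = 0, psi1 = 0, phi2 = 0, psi2 = 0, phi3 = 0, psi3 = 0,
               omega_flags = "tt",
               source_id = sprintf("fix%02d", i), chain = "A",
               start = seq_len(counts[i]), stringsAsFactors = FALSE)))
  build_database(recs)
}

# random self-avoiding-ish chain angles (interior angles defined)
random_chain_angles <- function(n) {
  list(phi = c(NA, stats::runif(n - 1, -pi, pi)),
       psi = c(stats::runif(n - 1, -pi, pi), NA))
}

chignolin_table1_counts <- c(994, 710, 1541, 1030, 1446, 1779, 545, 240)
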