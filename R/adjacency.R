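# Per-tripeptide adjacency graphs over conformation libraries, vertex
# densities, and goal-heuristic tables.
#
# Edge rule: (u, v) is an edge iff dc(u, v) < theta and d(u, v) < theta + xi,
# where d is the six-angle angular RMSD and dc its central-residue
# restriction. Every edge carries its d as weight.

# all-pairs wrapped-squared-distance matrices for a conformation matrix;
# returns list(d = full angular RMSD, dc = central distance)
pairwise_distances <- function(conf, central_norm = "per-angle") {
  n <- nrow(conf)
  if (n == 0) return(list(d = matrix(0, 0, 0), dc = matrix(0, 0, 0)))
  s6 <- matrix(0, n, n)
  s2 <- matrix(0, n, n)
  for (j in seq_len(6)) {
    dj <- angle_diff(outer(conf[, j], conf[, j], "-"), 0)^2
    s6 <- s6 + dj
    if (j %in% c(3, 4)) s2 <- s2 + dj
  }
  dc <- if (central_norm == "per-angle") sqrt(s2 / 2) else sqrt(s2 / 6)
  list(d = sqrt(s6 / 6), dc = dc)
}

#' Build the adjacency graph of one conformation library
#'
#' @param conf n-by-6 conformation matrix (one tripeptide library), or a
#'   library list with a `conf` element.
#' @param theta adjacency threshold on the central distance, radians.
#' @param xi tolerance margin added to `theta` for the full-distance test,
#'   radians (default 0.35).
#' @param central_norm normalisation of the central distance, see
#'   [central_distance()].
#' @return list of class `adjacency_graph`: `n`, `edges` (matrix with
#'   columns `u`, `v`, `d`; `u < v`), `theta`, `xi`, `central_norm`.
#' @export
build_adjacency_graph <- function(conf, theta, xi = 0.35,
                                  central_norm = "per-angle") {
  if (is.list(conf) && !is.null(conf$conf)) conf <- conf$conf
  stopifnot(is.matrix(conf), ncol(conf) == 6, theta > 0, xi >= 0)
  dm <- pairwise_distances(conf, central_norm)
  n <- nrow(conf)
  adj <- dm$dc < theta & dm$d < theta + xi
  adj[!upper.tri(adj)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  edges <- cbind(u = idx[, 1], v = idx[, 2], d = dm$d[idx])
  if (nrow(edges) > 1) edges <- edges[order(edges[, 1], edges[, 2]), ,
                                      drop = FALSE]
  structure(list(n = n, edges = edges, theta = theta, xi = xi,
                 central_norm = central_norm),
            class = "adjacency_graph")
}

graph_as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = graph$n, directed = FALSE)
  if (nrow(graph$edges) > 0)
    g <- igraph::add_edges(g, t(graph$edges[, 1:2]),
                           weight = graph$edges[, 3])
  g
}

#' Tune the adjacency threshold of a library
#'
#' Returns the smallest theta on the grid `grid_step, 2*grid_step, ...` for
#' which the adjacency graph has exactly one connected component — the
#' smallest threshold making every conformation reachable, our
#' operationalisation of "single component with moderate connectivity".
#'
#' @inheritParams build_adjacency_graph
#' @param grid_step grid resolution in radians (default 0.05).
#' @param theta_max largest grid value tried; the central distance is
#'   bounded by pi, so the default always terminates for a connectable
#'   library.
#' @param key optional key name used in error messages.
#' @return the tuned theta (radians).
#' @export
tune_theta <- function(conf, xi = 0.35, grid_step = 0.05,
                       central_norm = "per-angle",
                       theta_max = pi + grid_step, key = NULL) {
  if (is.list(conf) && !is.null(conf$conf)) conf <- conf$conf
  stopifnot(nrow(conf) >= 1, grid_step > 0)
  if (nrow(conf) == 1) return(grid_step)
  dm <- pairwise_distances(conf, central_norm)
  for (theta in seq(grid_step, theta_max, by = grid_step)) {
    adj <- dm$dc < theta & dm$d < theta + xi
    diag(adj) <- FALSE
    if (connected_components(adj) == 1) return(theta)
  }
  stop("no theta on the grid connects the library",
       if (!is.null(key)) paste0(" for key ", key))
}

# number of connected components of a logical adjacency matrix (union-find)
connected_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    a <- find(idx[r, 1]); b <- find(idx[r, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Vertex densities of an adjacency graph
#'
#' `rho(v) = 1 + #` graph neighbours of `v` at full distance `d < zeta`.
#' Density is a proxy for the probability of existence of the conformation
#' (dense graph regions are the energetically favourable ones).
#'
#' @param graph an `adjacency_graph`.
#' @param zeta density radius in radians (default 0.2); must be smaller
#'   than the graph's adjacency threshold theta.
#' @return integer vector of densities, one per vertex, each >= 1.
#' @export
compute_density <- function(graph, zeta = 0.2) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (zeta >= graph$theta)
    stop("zeta (", zeta, ") must be smaller than theta (", graph$theta, ")")
  rho <- rep(1L, graph$n)
  e <- graph$edges
  close_e <- e[e[, 3] < zeta, , drop = FALSE]
  if (nrow(close_e) > 0) {
    tab <- table(factor(c(close_e[, 1], close_e[, 2]),
                        levels = seq_len(graph$n)))
    rho <- rho + as.integer(tab)
  }
  rho
}

#' Shortest-path goal heuristic of an adjacency graph
#'
#' For each vertex, the shortest-path distance to `goal_vertex` with edge
#' weights d. This is a lower bound on the d-length any feasible transition
#' path can spend in this variable, because the graph search relaxes the
#' overlap and collision constraints.
#'
#' @param graph an `adjacency_graph`.
#' @param goal_vertex index of the goal conformation.
#' @return numeric vector `h` with `h[goal_vertex] == 0`; unreachable
#'   vertices get `Inf` (ranked last by the cost function, never an error).
#' @export
precompute_goal_heuristic <- function(graph, goal_vertex) {
  stopifnot(inherits(graph, "adjacency_graph"),
            goal_vertex >= 1, goal_vertex <= graph$n)
  g <- graph_as_igraph(graph)
  as.numeric(igraph::distances(g, v = goal_vertex,
                               weights = igraph::E(g)$weight,
                               algorithm = "dijkstra")[1, ])
}

# adjacency list representation: per vertex, a list with integer `to` and
# numeric `d`
graph_neighbors <- function(graph) {
  nb <- vector("list", graph$n)
  for (i in seq_len(graph$n)) nb[[i]] <- list(to = integer(0), d = numeric(0))
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    u <- as.integer(e[r, 1]); v <- as.integer(e[r, 2])
    d <- unname(e[r, 3])
    nb[[u]]$to <- c(nb[[u]]$to, v); nb[[u]]$d <- c(nb[[u]]$d, d)
    nb[[v]]$to <- c(nb[[v]]$to, u); nb[[v]]$d <- c(nb[[v]]$d, d)
  }
  nb
}

#' Index a database: adjacency graphs and densities for every key
#'
#' For each non-empty library, tunes theta (unless given), builds the
#' adjacency graph and computes vertex densities.
#'
#' @param db a `tripeptide_db`.
#' @param xi tolerance margin, radians (default 0.35).
#' @param zeta density radius, radians (default 0.2).
#' @param grid_step theta tuning grid, radians (default 0.05).
#' @param theta optional fixed theta applied to every key (skips tuning).
#' @param central_norm see [central_distance()].
#' @return the database with `graph`, `rho`, `theta` filled per library.
#' @export
index_database <- function(db, xi = 0.35, zeta = 0.2, grid_step = 0.05,
                           theta = NULL, central_norm = "per-angle") {
  stopifnot(inherits(db, "tripeptide_db"))
  for (k in names(db$libraries)) {
    lib <- db$libraries[[k]]
    th <- if (is.null(theta))
      tune_theta(lib$conf, xi = xi, grid_step = grid_step,
                 central_norm = central_norm, key = k)
    else theta
    if (!is.null(theta) && zeta >= th)
      stop("zeta must be smaller than theta")
    g <- build_adjacency_graph(lib$conf, theta = th, xi = xi,
                               central_norm = central_norm)
    # a tuned theta can still be <= zeta for tightly clustered libraries;
    # lift it to the first grid value above zeta so the density is defined
    while (is.null(theta) && g$theta <= zeta) {
      g <- build_adjacency_graph(lib$conf, theta = g$theta + grid_step,
                                 xi = xi, central_norm = central_norm)
    }
    lib$graph <- unclass(g)[c("n", "edges", "theta", "xi", "central_norm")]
    lib$graph <- structure(lib$graph, class = "adjacency_graph")
    lib$theta <- g$theta
    lib$rho <- compute_density(g, zeta = zeta)
    lib$zeta <- zeta
    db$libraries[[k]] <- lib
  }
  db$meta$params <- utils::modifyList(
    db$meta$params,
    list(xi = xi, zeta = zeta, grid_step = grid_step,
         central_norm = central_norm))
  db
}
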