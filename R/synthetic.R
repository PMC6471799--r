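# Synthetic tripeptide databases and toy search problems with known
# structure, so every module is exercisable without any external structure
# set. Basins emulate the Ramachandran regions (alpha, beta, PPII); samples
# are wrapped-normal draws around basin centers.

#' Specify a Ramachandran-like basin
#'
#' @param phi,psi basin center in radians.
#' @param spread isotropic wrapped-normal standard deviation in radians.
#' @param weight mixture weight (normalised over the basin list at
#'   sampling time).
#' @return list of class `basin_spec`.
#' @export
basin <- function(phi, psi, spread = 0.15, weight = 1) {
  stopifnot(spread >= 0, weight > 0)
  structure(list(phi = wrap_angle(phi), psi = wrap_angle(psi),
                 spread = spread, weight = weight), class = "basin_spec")
}

#' Canonical backbone basins
#'
#' Approximate Ramachandran basin centers: alpha-helix (-1.1, -0.8), beta
#' (-2.1, 2.3), polyproline II (-1.3, 2.6) radians.
#'
#' @param which subset of `c("alpha", "beta", "ppii")`.
#' @param spread per-basin spread in radians.
#' @return list of [basin()] objects.
#' @export
ramachandran_basins <- function(which = c("alpha", "beta", "ppii"),
                                spread = 0.15) {
  all <- list(alpha = basin(-1.1, -0.8, spread),
              beta = basin(-2.1, 2.3, spread),
              ppii = basin(-1.3, 2.6, spread))
  all[match.arg(which, several.ok = TRUE)]
}

sample_basin_angles <- function(basins, n) {
  w <- vapply(basins, `[[`, numeric(1), "weight")
  pick <- sample.int(length(basins), n, replace = TRUE, prob = w / sum(w))
  phi <- psi <- numeric(n)
  for (q in seq_len(n)) {
    b <- basins[[pick[q]]]
    phi[q] <- wrap_angle(stats::rnorm(1, b$phi, b$spread))
    psi[q] <- wrap_angle(stats::rnorm(1, b$psi, b$spread))
  }
  cbind(phi = phi, psi = psi)
}

#' Generate a synthetic tripeptide database
#'
#' Each conformation draws each residue position's (phi, psi) from a basin
#' mixture by wrapped-normal sampling. Deterministic given `seed`; the
#' database metadata marks it synthetic.
#'
#' @param keys character vector of tripeptide keys (one-letter codes).
#' @param basins either a length-3 list (one basin list per residue
#'   position, shared by all keys) or a named list keyed by tripeptide,
#'   each element a length-3 list of basin lists.
#' @param count conformations per key (single value or one per key).
#' @param seed integer RNG seed.
#' @return a `tripeptide_db` with `meta$synthetic = TRUE`.
#' @export
generate_synthetic_database <- function(keys, basins = NULL, count = 50,
                                        seed = 1L) {
  stopifnot(all(valid_key(keys)), all(count >= 1))
  count <- rep_len(count, length(keys))
  if (is.null(basins)) basins <- rep(list(ramachandran_basins()), 3)
  per_key <- !is.null(names(basins)) && all(keys %in% names(basins))
  set.seed(seed)
  recs <- list()
  for (qi in seq_along(keys)) {
    k <- keys[qi]
    bas <- if (per_key) basins[[k]] else basins
    stopifnot(length(bas) == 3)
    ang <- lapply(1:3, function(p) sample_basin_angles(bas[[p]], count[qi]))
    recs[[qi]] <- data.frame(
      key = k,
      phi1 = ang[[1]][, "phi"], psi1 = ang[[1]][, "psi"],
      phi2 = ang[[2]][, "phi"], psi2 = ang[[2]][, "psi"],
      phi3 = ang[[3]][, "phi"], psi3 = ang[[3]][, "psi"],
      omega_flags = "tt",
      source_id = sprintf("synth-%s", k), chain = "A",
      start = seq_len(count[qi]), stringsAsFactors = FALSE)
  }
  build_database(do.call(rbind, recs),
                 meta = list(synthetic = TRUE,
                             params = list(seed = seed, count = count)))
}

#' Mini-Chignolin synthetic fixture
#'
#' A demonstration database for the eight tripeptide keys of Chignolin
#' (GYDPETGTWG), built the way a real library is: by slicing full-chain
#' conformations into overlapping tripeptide windows. The chain states are
#' samples along an idealised turn-formation coordinate t in [0, 1]:
#' every residue starts in the beta region, and residues 5-8 (the
#' turn-forming half of the hairpin) interpolate to alpha-like turn angles
#' as t goes to 1. Each of `count` samples of t contributes one window per
#' key, with a small wrapped-normal jitter emulating structure-to-structure
#' variability; because the windows come from sliced chains, the overlap
#' identities between consecutive keys hold (up to jitter) at matching t,
#' exactly as for windows cut from one experimental structure. Keys whose
#' central residue turns carry `count` samples; keys where only a flank
#' residue moves carry a half-resolution track (elementary transitions focus on the
#' central residue, so these values change without a constraint of their
#' own); fully static keys hold a single conformation, as a rigid strand
#' region would.
#'
#' Fully folded and fully extended chain states live at the last and first
#' conformation index of every key, so `rep(1, 8)` and the per-key counts
#' give a natural extended-to-folded search problem. Deliberately simpler
#' than a structure-derived library: one folding coordinate instead of the
#' multimodal, neighbour-dependent Ramachandran statistics of real
#' tripeptides.
#'
#' @param count conformations per moving key (default 30).
#' @param seed RNG seed for the jitter.
#' @param jitter wrapped-normal jitter standard deviation in radians.
#' @return an unindexed synthetic `tripeptide_db` for the Chignolin keys.
#' @export
mini_chignolin_db <- function(count = 30, seed = 7L, jitter = 0.02) {
  spec <- decompose_sequence("GYDPETGTWG")
  n <- spec$n
  beta <- c(-2.1, 2.3)
  turn <- c(-1.1, -0.8)
  turning <- 5:8
  res_angles <- function(t) {
    phi <- rep(beta[1], n)
    psi <- rep(beta[2], n)
    phi[turning] <- beta[1] + t * (turn[1] - beta[1])
    psi[turning] <- beta[2] + t * (turn[2] - beta[2])
    list(phi = phi, psi = psi)
  }
  # elementary transitions act on a variable's central residue, so keys
  # whose central residue turns carry the full corridor; keys where only a
  # flank residue moves get a coarse track (their values change without an
  # overlap constraint of their own and would otherwise offer the search an
  # unbounded supply of near-free lateral moves); fully static keys hold a
  # single conformation
  central_moving <- (seq_along(spec$keys) + 1) %in% turning
  flank_moving <- !central_moving & vapply(seq_along(spec$keys),
    function(i) any((i:(i + 2)) %in% turning), logical(1))
  counts <- ifelse(central_moving, count,
                   ifelse(flank_moving, as.integer(ceiling(count / 2)), 1L))
  set.seed(seed)
  recs <- do.call(rbind, lapply(seq_along(spec$keys), function(i) {
    m <- counts[i]
    tfrac <- if (m > 1) (seq_len(m) - 1) / (m - 1) else 1
    rows <- lapply(seq_len(m), function(j) {
      a <- res_angles(tfrac[j])
      idx <- i:(i + 2)
      w <- wrap_angle(as.numeric(rbind(a$phi[idx], a$psi[idx])) +
                        stats::rnorm(6, 0, jitter))
      data.frame(key = spec$keys[i],
                 phi1 = w[1], psi1 = w[2], phi2 = w[3], psi2 = w[4],
                 phi3 = w[5], psi3 = w[6], omega_flags = "tt",
                 source_id = sprintf("synth-%s", spec$keys[i]),
                 chain = "A", start = j, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  build_database(recs, meta = list(synthetic = TRUE,
                                   params = list(seed = seed, count = count,
                                                 jitter = jitter)))
}

#' Extended and folded states of the mini-Chignolin fixture
#'
#' @param db a [mini_chignolin_db()] database.
#' @return list with integer assignments `extended` (all variables at their
#'   first, t = 0 conformation) and `folded` (all at their last, t = 1).
#' @export
mini_chignolin_states <- function(db) {
  spec <- decompose_sequence("GYDPETGTWG")
  sizes <- vapply(spec$keys, function(k)
    nrow(query_conformations(db, k)$conf), integer(1))
  list(extended = rep(1L, length(sizes)), folded = unname(sizes))
}

#' Generate a toy transition problem with an exhaustive certificate
#'
#' Builds a small synthetic database over `n_vars` state variables with
#' `values_per_var` conformations each, indexes it, picks start and goal
#' states, and computes a brute-force certificate by product-space BFS
#' under exactly the same feasibility rules the search uses.
#'
#' Connectivity patterns: `"corridor"` lays the conformations of every key
#' along a single angular corridor (one feasible route, certificate length
#' known by construction); `"random"` samples basin mixtures and random
#' endpoints; `"split"` draws two well-separated clusters with start and
#' goal in different clusters and a fixed small theta, so no path exists.
#'
#' @param n_vars number of state variables (protein length `n_vars + 2`).
#' @param values_per_var domain size per variable.
#' @param connectivity `"corridor"`, `"random"` or `"split"`.
#' @param seed RNG seed.
#' @param eps overlap tolerance of the generated problem.
#' @param collision_model optional [collision_model()]; default `NULL`
#'   (pure transition-system fixture).
#' @param f failure count of the problem (default `Inf`: relaxation off,
#'   so the problem searched equals the certified transition system).
#' @return list with `problem` (a [transition_problem()]) and
#'   `certificate` (list `reachable`, `n_steps`, `n_states`).
#' @export
generate_toy_problem <- function(n_vars = 3, values_per_var = 6,
                                 connectivity = c("corridor", "random",
                                                  "split"),
                                 seed = 1L, eps = 0.35,
                                 collision_model = NULL, f = Inf) {
  connectivity <- match.arg(connectivity)
  stopifnot(n_vars >= 1, values_per_var >= 2,
            values_per_var^n_vars <= 1e6)
  set.seed(seed)
  sequence <- sample(setdiff(AA1, "G"), n_vars + 2, replace = TRUE)
  spec <- decompose_sequence(sequence)
  m <- values_per_var

  if (connectivity == "corridor") {
    # conformations strung along one angular line; adjacent values differ
    # by `step` in every angle, so the graph is a path and consecutive
    # variables stay mutually consistent at matching positions
    step <- 0.15
    recs <- do.call(rbind, lapply(unique(spec$keys), function(k) {
      base <- seq(0, by = step, length.out = m)
      data.frame(key = k,
                 phi1 = base, psi1 = base, phi2 = base, psi2 = base,
                 phi3 = base, psi3 = base,
                 omega_flags = "tt", source_id = paste0("toy-", k),
                 chain = "A", start = seq_len(m), stringsAsFactors = FALSE)
    }))
    db <- build_database(recs, meta = list(synthetic = TRUE))
    db <- index_database(db, xi = 0.35, theta = step * 1.5, zeta = 0.1)
    s0 <- rep(1L, n_vars)
    sg <- rep(as.integer(m), n_vars)
  } else if (connectivity == "split") {
    # two tight clusters far apart; theta below the gap disconnects them
    recs <- do.call(rbind, lapply(unique(spec$keys), function(k) {
      half <- ceiling(m / 2)
      centers <- c(rep(-1.5, half), rep(1.5, m - half))
      jit <- function() wrap_angle(centers + stats::rnorm(m, 0, 0.05))
      data.frame(key = k,
                 phi1 = jit(), psi1 = jit(), phi2 = jit(), psi2 = jit(),
                 phi3 = jit(), psi3 = jit(),
                 omega_flags = "tt", source_id = paste0("toy-", k),
                 chain = "A", start = seq_len(m), stringsAsFactors = FALSE)
    }))
    db <- build_database(recs, meta = list(synthetic = TRUE))
    db <- index_database(db, xi = 0.35, theta = 0.8, zeta = 0.1)
    s0 <- rep(1L, n_vars)
    sg <- rep(as.integer(m), n_vars)
  } else {
    # one diffuse basin: pairwise angle differences straddle eps, so
    # reachability genuinely varies from seed to seed
    db <- generate_synthetic_database(
      unique(spec$keys),
      basins = rep(list(list(basin(-1.1, -0.8, 0.22))), 3),
      count = m, seed = seed + 1L)
    db <- index_database(db, xi = 0.35, zeta = 0.2)
    sizes <- vapply(spec$keys, function(k)
      nrow(query_conformations(db, k)$conf), integer(1))
    s0 <- vapply(sizes, function(sz) sample.int(sz, 1), integer(1))
    sg <- vapply(sizes, function(sz) sample.int(sz, 1), integer(1))
  }

  problem <- transition_problem(spec, db, s0, sg, eps = eps, f = f,
                                collision_model = collision_model,
                                seed = seed, validate = FALSE)
  list(problem = problem, certificate = bfs_certificate(problem))
}

#' Exhaustive product-space reachability certificate
#'
#' Breadth-first search over complete states from `s0`, expanding every
#' graph-adjacent single-variable change that passes the same feasibility
#' test the search uses (fixed `eps`, no relaxation). Independent of the
#' depth-first machinery: no cost function, no ordering heuristics, no
#' visited-set sharing.
#'
#' @param problem a [transition_problem()]; the product of its domain
#'   sizes must stay oracle-checkable (<= 1e6).
#' @param max_states cap on explored states.
#' @return list with `reachable` (logical), `n_steps` (shortest feasible
#'   path length in transitions, `NA` if unreachable), `n_states`
#'   (explored).
#' @export
bfs_certificate <- function(problem, max_states = 1e6) {
  nv <- length(problem$spec$keys)
  sizes <- vapply(problem$libs, function(l) nrow(l$conf), integer(1))
  stopifnot(prod(sizes) <= max_states)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  s0 <- problem$s0
  sg <- problem$sg
  seen[[state_key(s0)]] <- TRUE
  if (identical(as.integer(s0), as.integer(sg)))
    return(list(reachable = TRUE, n_steps = 0L, n_states = 1L))
  frontier <- list(s0)
  n_states <- 1L
  depth <- 0L
  while (length(frontier) > 0) {
    depth <- depth + 1L
    nxt <- list()
    for (s in frontier) {
      for (i in seq_len(nv)) {
        for (v in problem$neighbors[[i]][[s[i]]]$to) {
          s2 <- s
          s2[i] <- v
          key <- state_key(s2)
          if (!is.null(seen[[key]])) next
          chk <- feasible_transition(problem, s, i, v, eps = problem$eps)
          if (!chk$feasible) next
          seen[[key]] <- TRUE
          n_states <- n_states + 1L
          if (identical(as.integer(s2), as.integer(sg)))
            return(list(reachable = TRUE, n_steps = depth,
                        n_states = n_states))
          nxt[[length(nxt) + 1L]] <- s2
        }
      }
    }
    frontier <- nxt
  }
  list(reachable = FALSE, n_steps = NA_integer_, n_states = n_states)
}
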