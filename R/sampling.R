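# Incremental ensemble sampling: random collision-free, overlap-consistent
# states assembled variable by variable from the database.

#' Sample one random consistent, collision-free state
#'
#' Assigns state variables left to right: variable 1 uniformly over its
#' domain, variable i uniformly over the values whose shared angles agree
#' with the already-fixed left neighbour within `eps`. After each
#' assignment the partial chain (residues 1..i+2) is assembled and checked
#' for collisions; a colliding or consistency-dead-end prefix triggers
#' bounded chronological backtracking. Uses R's global RNG stream; call
#' `set.seed()` for reproducibility.
#'
#' @inheritParams chain_angles_from_state
#' @param eps overlap tolerance in radians (default 0.35).
#' @param collision_model a [collision_model()], or `NULL` to skip steric
#'   checks.
#' @param geom a [rigid_geometry()].
#' @param max_attempts total candidate evaluations before giving up
#'   (default `200 * number of variables`).
#' @return integer state assignment, or `NULL` when the retry budget is
#'   exhausted (caller may reseed and retry).
#' @export
sample_state <- function(spec, db, eps = 0.35, collision_model = NULL,
                         geom = rigid_geometry(), max_attempts = NULL) {
  libs <- spec_libraries(spec, db)
  nv <- length(libs)
  if (is.null(max_attempts)) max_attempts <- 200L * nv
  sizes <- vapply(libs, function(l) nrow(l$conf), integer(1))

  consistent_pool <- function(i, left_v) {
    a <- libs[[i - 1]]$conf[left_v, ]
    conf <- libs[[i]]$conf
    ok <- angle_diff(conf[, "phi1"], a["phi2"]) < eps &
      angle_diff(conf[, "psi1"], a["psi2"]) < eps &
      angle_diff(conf[, "phi2"], a["phi3"]) < eps &
      angle_diff(conf[, "psi2"], a["psi3"]) < eps
    which(ok)
  }
  partial_collides <- function(state, i) {
    if (is.null(collision_model)) return(FALSE)
    # residues 1..i+2 are determined by variables 1..i
    n_res <- i + 2
    phi <- psi <- numeric(n_res)
    phi[1] <- libs[[1]]$conf[state[1], "phi1"]
    psi[1] <- libs[[1]]$conf[state[1], "psi1"]
    for (j in 2:(n_res - 1)) {
      phi[j] <- libs[[j - 1]]$conf[state[j - 1], "phi2"]
      psi[j] <- libs[[j - 1]]$conf[state[j - 1], "psi2"]
    }
    phi[n_res] <- libs[[i]]$conf[state[i], "phi3"]
    psi[n_res] <- libs[[i]]$conf[state[i], "psi3"]
    ch <- reconstruct_backbone(spec$sequence[seq_len(n_res)],
                               list(phi = phi, psi = psi), geom)
    detect_collisions(ch, collision_model)$collision
  }

  state <- integer(nv)
  pools <- vector("list", nv)
  attempts <- 0L
  i <- 1L
  pools[[1]] <- sample(sizes[1])
  while (i >= 1L && i <= nv) {
    if (attempts >= max_attempts) return(NULL)
    if (length(pools[[i]]) == 0) {
      i <- i - 1L # backtrack: the prefix admits no extension
      next
    }
    v <- pools[[i]][1]
    pools[[i]] <- pools[[i]][-1]
    attempts <- attempts + 1L
    state[i] <- v
    if (partial_collides(state, i)) next
    if (i == nv) return(state)
    i <- i + 1L
    pool <- consistent_pool(i, state[i - 1])
    pools[[i]] <- if (length(pool) > 1) sample(pool) else pool
  }
  NULL
}

#' Sample an ensemble of random states
#'
#' `n` independent [sample_state()] draws; per-state seeds are derived
#' deterministically from `seed`, so any subset is reproducible.
#'
#' @inheritParams sample_state
#' @param n ensemble size.
#' @param seed integer master seed.
#' @return list with `states` (list of assignments), `failed` (indices of
#'   draws that exhausted their retry budget), `seeds` (per-state seeds).
#' @export
sample_ensemble <- function(spec, db, n, eps = 0.35, collision_model = NULL,
                            geom = rigid_geometry(), seed = 1L,
                            max_attempts = NULL) {
  stopifnot(n >= 0)
  set.seed(seed)
  seeds <- if (n > 0) sample.int(.Machine$integer.max, n) else integer(0)
  states <- vector("list", n)
  failed <- integer(0)
  for (j in seq_len(n)) {
    set.seed(seeds[j])
    s <- sample_state(spec, db, eps = eps,
                      collision_model = collision_model, geom = geom,
                      max_attempts = max_attempts)
    if (is.null(s)) failed <- c(failed, j) else states[[j]] <- s
  }
  list(states = states, failed = failed, seeds = seeds)
}
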