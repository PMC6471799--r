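# Heuristically-guided depth-first search (HDFS) over the product of
# tripeptide domains: feasible elementary transitions (overlap constraints
# + collision-free), cost-ordered candidate filtering, chronological
# backtracking with loop avoidance, and the epsilon relaxation schedule.

#' Define a conformational transition search problem
#'
#' Bundles the protein decomposition, an indexed database, start and goal
#' states, the feasibility tolerances and the heuristic weights, and
#' precomputes the per-variable goal-heuristic tables h (shortest path to
#' the goal value in each adjacency graph, edge weights d).
#'
#' @param spec a [decompose_sequence()] result.
#' @param db an indexed `tripeptide_db` (see [index_database()]).
#' @param s0,sg start and goal state assignments (integer vectors, one
#'   conformation index per variable).
#' @param eps overlap tolerance in radians (default 0.35).
#' @param eps_relaxed relaxed tolerance applied after `f` consecutive
#'   transition failures (default 0.7); reset to `eps` after a successful
#'   transition. Must exceed `eps`.
#' @param f consecutive-failure count triggering relaxation (default 5;
#'   `Inf` disables relaxation).
#' @param w1,w2 heuristic weights of the goal-distance and density terms
#'   (default 1 and 1).
#' @param collision_model a [collision_model()], or `NULL` to skip steric
#'   checks (useful for pure transition-system fixtures).
#' @param geom a [rigid_geometry()] used to assemble chains for collision
#'   checking.
#' @param max_recursions recursion limit distinguishing "exhausted" from
#'   "no path exists" (default 1e6).
#' @param seed integer recorded with the problem; the deterministic search
#'   does not consume randomness, but the seed is part of the provenance of
#'   every result.
#' @param validate check that `s0` and `sg` are in range and collision-free
#'   (default TRUE).
#' @return object of class `transition_problem`.
#' @export
transition_problem <- function(spec, db, s0, sg, eps = 0.35,
                               eps_relaxed = 0.7, f = 5, w1 = 1, w2 = 1,
                               collision_model = NULL,
                               geom = rigid_geometry(),
                               max_recursions = 1e6, seed = 1L,
                               validate = TRUE) {
  stopifnot(inherits(spec, "protein_spec"), inherits(db, "tripeptide_db"),
            eps > 0, eps_relaxed >= eps, f >= 1, max_recursions >= 1)
  libs <- spec_libraries(spec, db)
  nv <- length(spec$keys)
  sizes <- vapply(libs, function(l) nrow(l$conf), integer(1))
  stopifnot(length(s0) == nv, length(sg) == nv,
            all(s0 >= 1), all(s0 <= sizes),
            all(sg >= 1), all(sg <= sizes))
  for (i in seq_len(nv)) {
    if (is.null(libs[[i]]$graph) || is.null(libs[[i]]$rho))
      stop("database not indexed for key ", spec$keys[i],
           "; run index_database() first")
  }
  neighbors <- lapply(libs, function(l) graph_neighbors(l$graph))
  h <- lapply(seq_len(nv), function(i)
    precompute_goal_heuristic(libs[[i]]$graph, sg[i]))
  prob <- structure(list(
    spec = spec, db = db, libs = libs, neighbors = neighbors, h = h,
    s0 = as.integer(s0), sg = as.integer(sg),
    eps = eps, eps_relaxed = eps_relaxed, f = f, w1 = w1, w2 = w2,
    collision_model = collision_model, geom = geom,
    max_recursions = max_recursions, seed = as.integer(seed)),
    class = "transition_problem")
  if (validate) {
    for (nm in c("s0", "sg")) {
      s <- prob[[nm]]
      if (state_collides(prob, s))
        stop(nm, " is not collision-free")
    }
  }
  prob
}

#' @export
print.transition_problem <- function(x, ...) {
  cat(sprintf("Transition problem: %d variables (%s)\n",
              length(x$spec$keys), paste(x$spec$sequence, collapse = "")))
  cat(sprintf("  eps %.3g (relaxed %.3g after %s failures), w1 %.3g, w2 %.3g\n",
              x$eps, x$eps_relaxed, format(x$f), x$w1, x$w2))
  cat(sprintf("  collisions: %s, max recursions: %g, seed: %d\n",
              if (is.null(x$collision_model)) "off" else "on",
              x$max_recursions, x$seed))
  invisible(x)
}

state_collides <- function(problem, s) {
  if (is.null(problem$collision_model)) return(FALSE)
  ch <- chain_from_state(problem$spec, problem$db, s, problem$geom)
  detect_collisions(ch, problem$collision_model)$collision
}

#' Feasibility of one elementary transition
#'
#' A transition of variable `var_i` from its current value to `v_to` is
#' feasible when (i) the new central-residue angles agree with the current
#' values of the neighbouring variables within `eps` (four wrapped
#' inequalities; boundary variables check only existing neighbours), and
#' (ii) the resulting chain is collision-free.
#'
#' @param problem a [transition_problem()].
#' @param s current state assignment.
#' @param var_i index of the variable to change.
#' @param v_to target conformation index (must be graph-adjacent to
#'   `s[var_i]` for a legal elementary transition; adjacency itself is not
#'   re-checked here).
#' @param eps overlap tolerance; defaults to the problem's `eps`.
#' @return list with `feasible` (logical), `state` (the new assignment when
#'   feasible) and `reason` (`"overlap"` or `"collision"` otherwise).
#' @export
feasible_transition <- function(problem, s, var_i, v_to,
                                eps = problem$eps) {
  libs <- problem$libs
  nv <- length(libs)
  v_to <- as.integer(v_to)
  new_val <- libs[[var_i]]$conf[v_to, ]
  if (var_i > 1) {
    left <- libs[[var_i - 1]]$conf[s[var_i - 1], ]
    if (angle_diff(new_val["phi2"], left["phi3"]) >= eps ||
        angle_diff(new_val["psi2"], left["psi3"]) >= eps)
      return(list(feasible = FALSE, reason = "overlap"))
  }
  if (var_i < nv) {
    right <- libs[[var_i + 1]]$conf[s[var_i + 1], ]
    if (angle_diff(new_val["phi2"], right["phi1"]) >= eps ||
        angle_diff(new_val["psi2"], right["psi1"]) >= eps)
      return(list(feasible = FALSE, reason = "overlap"))
  }
  s2 <- s
  s2[var_i] <- v_to
  if (state_collides(problem, s2))
    return(list(feasible = FALSE, reason = "collision"))
  list(feasible = TRUE, state = s2)
}

#' Heuristic cost of an elementary transition
#'
#' `cost = d(v_from, v_to) + w1 * h(v_to) + w2 / rho(v_to)`: the edge
#' length, the shortest-path estimate of the remaining distance to the goal
#' value, and an inverse-density term favouring probable conformations.
#' `Inf` when the goal is unreachable from `v_to` in the adjacency graph.
#'
#' @inheritParams feasible_transition
#' @param v_from,v_to conformation indices; `v_to` must be adjacent to
#'   `v_from`.
#' @return numeric cost.
#' @export
transition_cost <- function(problem, var_i, v_from, v_to) {
  nb <- problem$neighbors[[var_i]][[v_from]]
  pos <- match(v_to, nb$to)
  if (is.na(pos)) stop("v_to is not adjacent to v_from")
  h <- problem$h[[var_i]][v_to]
  if (!is.finite(h)) return(Inf)
  nb$d[pos] + problem$w1 * h + problem$w2 / problem$libs[[var_i]]$rho[v_to]
}

state_key <- function(s) paste(s, collapse = ",")

#' Ordered feasible transitions of one variable
#'
#' Adjacent values of the variable's current conformation, minus those
#' whose resulting state was already visited (loop avoidance), minus
#' infeasible ones, sorted by increasing heuristic cost with ties broken by
#' conformation index.
#'
#' @inheritParams feasible_transition
#' @param visited environment used as a hash set of visited state keys, or
#'   `NULL` to skip loop filtering.
#' @return data frame with columns `v`, `cost`, `d`; attribute
#'   `n_infeasible` counts the candidates rejected by the feasibility test
#'   (feeds the relaxation failure counter).
#' @export
transition_filter <- function(problem, s, var_i, visited = NULL,
                              eps = problem$eps) {
  v_from <- s[var_i]
  nb <- problem$neighbors[[var_i]][[v_from]]
  keep <- rep(TRUE, length(nb$to))
  if (!is.null(visited) && length(nb$to) > 0) {
    for (q in seq_along(nb$to)) {
      s2 <- s
      s2[var_i] <- nb$to[q]
      if (!is.null(visited[[state_key(s2)]])) keep[q] <- FALSE
    }
  }
  to <- nb$to[keep]
  dd <- nb$d[keep]
  n_infeasible <- 0L
  feas <- logical(length(to))
  for (q in seq_along(to)) {
    r <- feasible_transition(problem, s, var_i, to[q], eps = eps)
    feas[q] <- r$feasible
    if (!r$feasible) n_infeasible <- n_infeasible + 1L
  }
  to <- to[feas]
  dd <- dd[feas]
  if (length(to) > 0) {
    rho <- problem$libs[[var_i]]$rho[to]
    h <- problem$h[[var_i]][to]
    cost <- dd + problem$w1 * h + problem$w2 / rho
    ord <- order(cost, to)
    out <- data.frame(v = to[ord], cost = cost[ord], d = dd[ord])
  } else {
    out <- data.frame(v = integer(0), cost = numeric(0), d = numeric(0))
  }
  attr(out, "n_infeasible") <- n_infeasible
  out
}

#' Heuristically-guided depth-first search for a feasible path
#'
#' Depth-first search over the product of tripeptide domains with
#' chronological backtracking. At each state the candidate set E is the
#' union over all state variables of the graph-adjacent values, ordered
#' globally by the heuristic cost (ties by variable then value index);
#' feasibility (overlap constraints, collisions) is evaluated lazily in
#' that order, so the explored tree is the cost-ordered one while the
#' expensive steric test runs only on candidates actually tried. Complete
#' states are never revisited. After `f` consecutive feasibility failures
#' the overlap tolerance is relaxed to `eps_relaxed`, and reset to `eps` by
#' the next successful transition. Deterministic given the problem (the
#' recorded seed is provenance, not a randomness source).
#'
#' @param problem a [transition_problem()].
#' @return object of class `transition_path`: `status` (`"success"`,
#'   `"no_path"`, or `"limit"`), `transitions` (data frame `var`, `from`,
#'   `to`, `d`, `eps`), `states` (list of assignments along the path,
#'   including both endpoints), `diagnostics` (recursions, backtracks,
#'   relaxations), `metrics` (see [path_metrics()]) and problem provenance.
#' @export
hdfs_search <- function(problem) {
  stopifnot(inherits(problem, "transition_problem"))
  nv <- length(problem$spec$keys)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  recursions <- 0L
  backtracks <- 0L
  relaxations <- 0L
  fail_count <- 0L
  eps_now <- problem$eps

  # E for a whole state: all graph neighbours of every variable's current
  # value, cost-ordered; feasibility is checked lazily at pop time
  state_queue <- function(s) {
    parts <- vector("list", nv)
    for (i in seq_len(nv)) {
      nb <- problem$neighbors[[i]][[s[i]]]
      if (length(nb$to) == 0) next
      cost <- nb$d + problem$w1 * problem$h[[i]][nb$to] +
        problem$w2 / problem$libs[[i]]$rho[nb$to]
      parts[[i]] <- data.frame(var = i, v = nb$to, cost = cost, d = nb$d)
    }
    q <- do.call(rbind, parts)
    if (is.null(q))
      return(data.frame(var = integer(0), v = integer(0),
                        cost = numeric(0), d = numeric(0)))
    q[order(q$cost, q$var, q$v), , drop = FALSE]
  }
  make_frame <- function(s, trans) {
    list(s = s, trans = trans, queue = state_queue(s))
  }
  finish <- function(status, stack) {
    trans_list <- Filter(Negate(is.null), lapply(stack, `[[`, "trans"))
    transitions <- if (length(trans_list))
      do.call(rbind, trans_list)
    else
      data.frame(var = integer(0), from = integer(0), to = integer(0),
                 d = numeric(0), eps = numeric(0))
    states <- lapply(stack, `[[`, "s")
    path <- structure(list(
      status = status,
      transitions = transitions,
      states = states,
      s0 = problem$s0, sg = problem$sg,
      keys = problem$spec$keys,
      sequence = paste(problem$spec$sequence, collapse = ""),
      params = list(eps = problem$eps, eps_relaxed = problem$eps_relaxed,
                    f = problem$f, w1 = problem$w1, w2 = problem$w2,
                    seed = problem$seed),
      diagnostics = list(recursions = recursions, backtracks = backtracks,
                         relaxations = relaxations)),
      class = "transition_path")
    path$metrics <- if (status == "success") path_metrics(path, problem$db)
                    else NULL
    path
  }

  visited[[state_key(problem$s0)]] <- TRUE
  stack <- list(make_frame(problem$s0, NULL))
  if (identical(as.integer(problem$s0), as.integer(problem$sg)))
    return(finish("success", stack))

  repeat {
    depth <- length(stack)
    if (depth == 0) return(finish("no_path", list(make_frame(problem$s0,
                                                             NULL))))
    fr <- stack[[depth]]
    if (nrow(fr$queue) == 0) {
      # dead end: every candidate of every variable tried at this state
      stack[[depth]] <- NULL
      backtracks <- backtracks + 1L
      next
    }
    cand <- fr$queue[1, ]
    fr$queue <- fr$queue[-1, , drop = FALSE]
    stack[[depth]] <- fr
    s2 <- fr$s
    s2[cand$var] <- cand$v
    if (!is.null(visited[[state_key(s2)]])) next # loop avoidance
    chk <- feasible_transition(problem, fr$s, cand$var, cand$v, eps_now)
    if (!chk$feasible) {
      fail_count <- fail_count + 1L
      if (fail_count >= problem$f && eps_now < problem$eps_relaxed) {
        eps_now <- problem$eps_relaxed
        relaxations <- relaxations + 1L
        # candidates already consumed at the strict tolerance become
        # eligible again: rebuild this state's queue so they are retried
        # under the relaxed eps (visited filtering still applies at pop)
        fr$queue <- state_queue(fr$s)
        stack[[depth]] <- fr
      }
      next
    }
    recursions <- recursions + 1L
    if (recursions > problem$max_recursions)
      return(finish("limit", stack))
    visited[[state_key(s2)]] <- TRUE
    fail_count <- 0L
    eps_used <- eps_now
    eps_now <- problem$eps
    trans <- data.frame(var = cand$var, from = fr$s[cand$var],
                        to = cand$v, d = cand$d, eps = eps_used)
    stack[[depth + 1L]] <- make_frame(s2, trans)
    if (identical(as.integer(s2), as.integer(problem$sg)))
      return(finish("success", stack))
  }
}

#' Re-validate a transition path step by step
#'
#' Independently replays every recorded transition: graph adjacency of each
#' step, the overlap constraints at the recorded tolerance, collision
#' freedom, and that the path connects `s0` to `sg`.
#'
#' @param path a `transition_path` with status `"success"`.
#' @param problem the original [transition_problem()].
#' @return `TRUE` (invisibly) if every step validates; otherwise stops with
#'   the first violated step.
#' @export
validate_path <- function(path, problem) {
  stopifnot(inherits(path, "transition_path"),
            identical(path$status, "success"))
  s <- problem$s0
  tr <- path$transitions
  for (r in seq_len(nrow(tr))) {
    i <- tr$var[r]
    stopifnot(s[i] == tr$from[r])
    nb <- problem$neighbors[[i]][[s[i]]]
    if (!(tr$to[r] %in% nb$to))
      stop("step ", r, ": target value not graph-adjacent")
    chk <- feasible_transition(problem, s, i, tr$to[r], eps = tr$eps[r])
    if (!chk$feasible)
      stop("step ", r, ": transition infeasible (", chk$reason, ")")
    s <- chk$state
  }
  if (!identical(as.integer(s), as.integer(problem$sg)))
    stop("path does not end at the goal state")
  invisible(TRUE)
}

#' @export
print.transition_path <- function(x, ...) {
  cat(sprintf("Transition path: %s\n", x$status))
  cat(sprintf("  %s (%d variables)\n", x$sequence, length(x$keys)))
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  steps %d, distance %.3f rad, density %.2f (per state)\n",
                m$steps, m$distance, m$density_per_state))
  }
  d <- x$diagnostics
  cat(sprintf("  recursions %d, backtracks %d, relaxations %d\n",
              d$recursions, d$backtracks, d$relaxations))
  invisible(x)
}

#' @export
summary.transition_path <- function(object, ...) {
  out <- c(list(status = object$status, sequence = object$sequence),
           object$metrics, object$diagnostics, object$params)
  class(out) <- "summary.transition_path"
  out
}

#' @export
print.summary.transition_path <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
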