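# A small shared corridor problem for most blocks (3 variables, path
# graphs, collision checks off).
corridor <- generate_toy_problem(3, 5, "corridor", seed = 101)

test_that("transition cost follows d + w1*h + w2/rho exactly", {
  pr <- corridor$problem
  # direct arithmetic case on a hand-built mock problem
  mock <- pr
  mock$neighbors[[1]][[1]] <- list(to = 2L, d = 0.3)
  mock$h[[1]][2] <- 1.2
  mock$libs[[1]]$rho[2] <- 4L
  expect_equal(transition_cost(mock, 1, 1L, 2L), 0.3 + 1.2 + 0.25)
  # goal value: h = 0, cost = d + w2/rho(goal)
  gv <- pr$sg[1]
  prev <- pr$neighbors[[1]][[gv]]$to[1]
  d_edge <- pr$neighbors[[1]][[prev]]$d[
    match(gv, pr$neighbors[[1]][[prev]]$to)]
  expect_equal(transition_cost(pr, 1, prev, gv),
               unname(d_edge + 1 / pr$libs[[1]]$rho[gv]))
  # non-adjacent pair is an error; Inf-h target costs Inf
  expect_error(transition_cost(pr, 1, 1L, 4L), "not adjacent")
  mock$h[[1]][2] <- Inf
  expect_equal(transition_cost(mock, 1, 1L, 2L), Inf)
})

test_that("feasibility enforces the four overlap inequalities and collisions", {
  pr <- corridor$problem
  s <- pr$s0
  # stepping variable 1 by one is feasible (differences 0.15 < 0.35)
  r <- feasible_transition(pr, s, 1, 2L)
  expect_true(r$feasible)
  expect_equal(r$state, c(2L, 1L, 1L))
  # jumping a middle variable two levels up breaks the overlap bound if
  # eps is tightened below the construction step
  r2 <- feasible_transition(pr, s, 2, 2L, eps = 0.1)
  expect_false(r2$feasible)
  expect_equal(r2$reason, "overlap")
  # collisions: a value that folds the chain onto itself is rejected with
  # the steric reason (clash established independently by the naive scan).
  # Database: every key holds the window of an extended chain (value 1)
  # plus windows sliced from random-angle chains, some of which clash.
  spec <- decompose_sequence("GYDPETGTWG")
  cm <- collision_model()
  slice_chain <- function(phi, psi, src, j) {
    do.call(rbind, lapply(seq_along(spec$keys), function(i)
      data.frame(key = spec$keys[i],
                 phi1 = phi[i], psi1 = psi[i], phi2 = phi[i + 1],
                 psi2 = psi[i + 1], phi3 = phi[i + 2], psi3 = psi[i + 2],
                 omega_flags = "tt", source_id = src, chain = "A",
                 start = 100 * j + i, stringsAsFactors = FALSE)))
  }
  recs <- slice_chain(rep(-2.1, 10), rep(2.3, 10), "ext", 0)
  set.seed(102)
  for (j in 1:6)
    recs <- rbind(recs, slice_chain(runif(10, -pi, pi),
                                    runif(10, -pi, pi),
                                    sprintf("rnd%d", j), j))
  dbx <- index_database(build_database(recs))
  s0 <- rep(1L, 8)
  prc <- transition_problem(spec, dbx, s0, s0, collision_model = cm)
  found <- FALSE
  for (i in seq_along(spec$keys)) {
    for (v in 2:7) {
      s2 <- s0
      s2[i] <- v
      ch <- chain_from_state(spec, dbx, s2)
      if (detect_collisions(ch, cm, method = "naive")$collision) {
        rr <- feasible_transition(prc, s0, i, v, eps = Inf)
        expect_false(rr$feasible)
        expect_equal(rr$reason, "collision")
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found) # the fixture does contain a self-clashing value
})

test_that("transition_filter orders candidates by cost with index ties", {
  pr <- corridor$problem
  s <- c(2L, 2L, 2L)
  fl <- transition_filter(pr, s, 2, visited = NULL)
  expect_true(all(fl$v %in% pr$neighbors[[2]][[2]]$to))
  costs <- vapply(fl$v, function(v) transition_cost(pr, 2, 2L, v),
                  numeric(1))
  expect_equal(fl$cost, costs)
  expect_false(is.unsorted(fl$cost))
  # all neighbours visited -> empty list
  visited <- new.env(hash = TRUE, parent = emptyenv())
  for (v in pr$neighbors[[2]][[2]]$to) {
    s2 <- s
    s2[2] <- v
    assign(paste(s2, collapse = ","), TRUE, envir = visited)
  }
  expect_equal(nrow(transition_filter(pr, s, 2, visited)), 0)
})

test_that("hdfs on trivial and corridor problems, with step revalidation", {
  # s0 == sg: success with an empty path
  pr0 <- corridor$problem
  pr0$sg <- pr0$s0
  p0 <- hdfs_search(pr0)
  expect_equal(p0$status, "success")
  expect_equal(nrow(p0$transitions), 0)
  expect_equal(p0$metrics$steps, 0)
  expect_equal(p0$metrics$distance, 0)
  # corridor: reachable, certificate agrees, every step revalidates
  expect_true(corridor$certificate$reachable)
  # shortest route raises each variable through its whole column
  expect_equal(corridor$certificate$n_steps, 3 * 4)
  p <- hdfs_search(corridor$problem)
  expect_equal(p$status, "success")
  expect_true(validate_path(p, corridor$problem))
  expect_identical(p$states[[length(p$states)]], corridor$problem$sg)
})

test_that("hdfs proves unreachability on split fixtures", {
  tp <- generate_toy_problem(3, 6, "split", seed = 103)
  expect_false(tp$certificate$reachable)
  p <- hdfs_search(tp$problem)
  expect_equal(p$status, "no_path")
  # the recursion limit gives a distinct status
  tp2 <- generate_toy_problem(3, 5, "corridor", seed = 104)
  tp2$problem$max_recursions <- 2
  expect_equal(hdfs_search(tp2$problem)$status, "limit")
})

test_that("epsilon relaxation unblocks a search and is recorded", {
  # two variables whose only route requires a 0.5-rad central jump:
  # infeasible at eps = 0.35, feasible at 0.7 after f failures
  step <- 0.5
  keys <- c("AAC", "ACA")
  recs <- do.call(rbind, lapply(keys, function(k) {
    base <- seq(0, by = step, length.out = 4)
    data.frame(key = k, phi1 = base, psi1 = base, phi2 = base, psi2 = base,
               phi3 = base, psi3 = base, omega_flags = "tt",
               source_id = paste0("r", k), chain = "A", start = 1:4,
               stringsAsFactors = FALSE)
  }))
  db <- build_database(recs)
  db <- index_database(db, xi = 0.35, theta = step * 1.5, zeta = 0.2)
  spec <- decompose_sequence("AACA")
  strict <- transition_problem(spec, db, c(1L, 1L), c(4L, 4L),
                               eps = 0.35, eps_relaxed = 0.35, f = Inf)
  expect_equal(hdfs_search(strict)$status, "no_path")
  # f = 2: a two-variable fixture only accrues two candidate failures
  # per dead end, so the default f = 5 could never be reached
  relaxed <- transition_problem(spec, db, c(1L, 1L), c(4L, 4L),
                                eps = 0.35, eps_relaxed = 0.7, f = 2)
  p <- hdfs_search(relaxed)
  expect_equal(p$status, "success")
  expect_gt(p$diagnostics$relaxations, 0)
  expect_true(any(p$transitions$eps == 0.7))
  expect_true(validate_path(p, relaxed))
})

test_that("identical problem and seed give byte-identical path logs", {
  tp <- generate_toy_problem(3, 6, "random", seed = 105)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_path_log(hdfs_search(tp$problem), f1)
  write_path_log(hdfs_search(tp$problem), f2)
  expect_identical(readLines(f1), readLines(f2))
  # round trip preserves transitions and metrics
  p <- read_path_log(f1)
  expect_equal(p$transitions, hdfs_search(tp$problem)$transitions)
})

test_that("path metrics and intermediates follow the recorded transitions", {
  p <- hdfs_search(corridor$problem)
  m <- path_metrics(p, corridor$problem$db)
  expect_equal(m$steps, nrow(p$transitions))
  expect_equal(m$distance, sum(p$transitions$d))
  # corridor densities are uniform (rho = 1), so both weightings agree
  expect_equal(m$density_per_state, 1)
  expect_equal(m$density_per_transition, 1)
  # recomputation from the stored transition list is invariant
  p2 <- p
  p2$states <- list()
  expect_equal(path_metrics(p2, corridor$problem$db), m)
  # intermediates: k = 1 gives the endpoints, larger k is monotone
  ends <- select_intermediates(p, 1)
  expect_identical(ends[[1]], corridor$problem$s0)
  expect_identical(ends[[2]], corridor$problem$sg)
  if (nrow(p$transitions) >= 10) {
    inter <- select_intermediates(p, 10)
    expect_equal(length(inter), 11)
    expect_identical(inter[[1]], corridor$problem$s0)
    expect_identical(inter[[11]], corridor$problem$sg)
  }
  # uniform-weight path: every 10th state at k = 10
  pu <- p
  pu$transitions <- data.frame(var = rep(1L, 100), from = 1:100,
                               to = 2:101, d = rep(0.1, 100),
                               eps = 0.35)
  pu$states <- lapply(0:100, function(i) c(i, 0L, 0L))
  pu$s0 <- pu$states[[1]]
  iu <- select_intermediates(pu, 10)
  expect_equal(vapply(iu, `[`, numeric(1), 1), seq(0, 100, by = 10))
})

test_that("sampled states validate and sampling is seed-reproducible", {
  db <- index_database(mini_chignolin_db(25, seed = 7))
  spec <- decompose_sequence("GYDPETGTWG")
  cm <- collision_model()
  set.seed(106)
  ok <- 0
  for (rep in 1:25) {
    s <- sample_state(spec, db, eps = 0.35, collision_model = cm)
    if (is.null(s)) next
    ok <- ok + 1
    expect_true(attr(check_overlap_consistency(spec, db, s, 0.35), "ok"))
    ch <- chain_from_state(spec, db, s)
    expect_false(detect_collisions(ch, cm)$collision)
  }
  expect_gt(ok, 15)
  # determinism
  set.seed(107)
  a <- sample_state(spec, db, collision_model = cm)
  set.seed(107)
  b <- sample_state(spec, db, collision_model = cm)
  expect_identical(a, b)
  # a mutually consistent database never backtracks (all values identical)
  db1 <- index_database(make_counts_db(spec$keys,
                                       rep(4, 8)), theta = 0.3, zeta = 0.2)
  expect_false(is.null(sample_state(spec, db1, max_attempts = 8)))
})

test_that("ensembles are reproducible and respect n", {
  db <- index_database(mini_chignolin_db(15, seed = 7))
  spec <- decompose_sequence("GYDPETGTWG")
  e0 <- sample_ensemble(spec, db, 0, seed = 9)
  expect_equal(length(e0$states), 0)
  e1 <- sample_ensemble(spec, db, 10, seed = 9)
  e2 <- sample_ensemble(spec, db, 10, seed = 9)
  expect_identical(e1$states, e2$states)
  for (s in e1$states[!vapply(e1$states, is.null, logical(1))])
    expect_true(attr(check_overlap_consistency(spec, db, s, 0.35), "ok"))
})
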