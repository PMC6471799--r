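test_that("sequence decomposition yields n - 2 overlapping variables", {
  spec <- decompose_sequence("GYDPETGTWG") # Chignolin
  expect_equal(length(spec$keys), 8)
  expect_equal(spec$keys[1], "GYD")
  expect_equal(spec$keys[8], "TWG")
  # DS119, 36 residues -> 34 variables
  ds119 <- "GSGQVRTIWVGGTPEELKKLKEEALLEAKKANIRVTFW"
  ds119 <- substr(ds119, 1, 36)
  expect_equal(length(decompose_sequence(ds119)$keys), 34)
  # minimal case and errors
  expect_equal(decompose_sequence("AAA")$keys, "AAA")
  expect_error(decompose_sequence("AA"), "at least 3")
  expect_error(decompose_sequence("AXB"), "non-standard")
  # property: count over random lengths, consecutive keys share two letters
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    sq <- sample(c("A", "G", "L", "S", "W"), n, replace = TRUE)
    sp <- decompose_sequence(sq)
    expect_equal(length(sp$keys), n - 2)
    if (n > 3)
      expect_true(all(substr(sp$keys[-1], 1, 2) ==
                        substr(sp$keys[-(n - 2)], 2, 3)))
  }
})

test_that("state slicing of a contiguous chain is self-consistent", {
  # slice one continuous chain into its own tripeptides, rebuild by the
  # central-residue rule and recover the source angles exactly
  set.seed(62)
  n <- 9
  seqc <- sample(c("A", "D", "E", "T"), n, replace = TRUE)
  phi <- runif(n, -pi, pi)
  psi <- runif(n, -pi, pi)
  spec <- decompose_sequence(seqc)
  recs <- do.call(rbind, lapply(seq_len(n - 2), function(i)
    data.frame(key = spec$keys[i],
               phi1 = phi[i], psi1 = psi[i],
               phi2 = phi[i + 1], psi2 = psi[i + 1],
               phi3 = phi[i + 2], psi3 = psi[i + 2],
               omega_flags = "tt", source_id = "self", chain = "A",
               start = i, stringsAsFactors = FALSE)))
  db <- build_database(recs)
  sizes <- vapply(spec$keys, function(k)
    nrow(query_conformations(db, k)$conf), integer(1))
  # pick, per variable, the index of its own window (keys can repeat)
  s <- vapply(seq_len(n - 2), function(i) {
    lib <- query_conformations(db, spec$keys[i])
    which(lib$source == paste("self", "A", i, sep = "|"))
  }, integer(1))
  ang <- chain_angles_from_state(spec, db, s)
  expect_equal(ang$phi, phi, tolerance = 1e-12)
  expect_equal(ang$psi, psi, tolerance = 1e-12)
  rep_ <- check_overlap_consistency(spec, db, s, eps = 1e-9)
  expect_true(attr(rep_, "ok"))
  expect_equal(max(rep_$max_violation), 0)
  expect_equal(state_rmsd(spec, db, s, s), 0)
})

test_that("chain assembly is local in the changed variable", {
  db <- index_database(mini_chignolin_db(15, seed = 7))
  spec <- decompose_sequence("GYDPETGTWG")
  set.seed(63)
  s1 <- vapply(spec$keys, function(k)
    sample.int(nrow(query_conformations(db, k)$conf), 1), integer(1))
  k <- 4
  s2 <- s1
  s2[k] <- if (s1[k] == 1) 2L else s1[k] - 1L
  a1 <- chain_angles_from_state(spec, db, s1)
  a2 <- chain_angles_from_state(spec, db, s2)
  changed <- which(a1$phi != a2$phi | a1$psi != a2$psi)
  expect_true(all(changed %in% k:(k + 2)))
})

test_that("overlap violations are localised and eps = Inf always passes", {
  db <- index_database(mini_chignolin_db(15, seed = 7))
  spec <- decompose_sequence("GYDPETGTWG")
  set.seed(64)
  s <- vapply(spec$keys, function(k)
    sample.int(nrow(query_conformations(db, k)$conf), 1), integer(1))
  rep_inf <- check_overlap_consistency(spec, db, s, eps = Inf)
  expect_true(attr(rep_inf, "ok"))
  expect_equal(nrow(rep_inf), 7)
})

test_that("search space size is an exact big-integer product", {
  spec <- decompose_sequence("GYDPETGTWG")
  db <- make_counts_db(spec$keys, chignolin_table1_counts)
  sz <- search_space_size(spec, db)
  # frozen value computed independently (Python arbitrary precision):
  # 994*710*1541*1030*1446*1779*545*240
  expect_equal(sz$size, "376909063980143113440000")
  expect_equal(sz$log10, sum(log10(chignolin_table1_counts)),
               tolerance = 1e-12)
  # trivial sizes
  db1 <- make_counts_db(c("AAA", "AAC"), c(1, 1))
  expect_equal(search_space_size(decompose_sequence("AAAC"), db1)$size, "1")
  db2 <- make_counts_db(c("AAA", "AAC"), c(2, 3))
  expect_equal(search_space_size(decompose_sequence("AAAC"), db2)$size, "6")
  # multiplicative and order-independent
  expect_equal(search_space_size(decompose_sequence("CAAA"),
                                 make_counts_db(c("CAA", "AAA"),
                                                c(3, 2)))$size, "6")
})

test_that("nearest_db_state matches an exhaustive per-variable scan", {
  db <- index_database(mini_chignolin_db(15, seed = 7))
  spec <- decompose_sequence("GYDPETGTWG")
  # expressible target: a target sliced from one contiguous chain has
  # every variable's own window in its domain at distance 0, so it is
  # recovered exactly (and is overlap-consistent, surviving the repair)
  set.seed(65)
  phi <- runif(10, -pi, pi)
  psi <- runif(10, -pi, pi)
  recs <- do.call(rbind, lapply(seq_len(8), function(i)
    data.frame(key = spec$keys[i],
               phi1 = phi[i], psi1 = psi[i], phi2 = phi[i + 1],
               psi2 = psi[i + 1], phi3 = phi[i + 2], psi3 = psi[i + 2],
               omega_flags = "tt", source_id = "zzself", chain = "A",
               start = i, stringsAsFactors = FALSE)))
  db_plus <- build_database(rbind(recs, do.call(rbind, lapply(
    names(db$libraries), function(k) {
      lib <- db$libraries[[k]]
      data.frame(key = k,
                 phi1 = lib$conf[, 1], psi1 = lib$conf[, 2],
                 phi2 = lib$conf[, 3], psi2 = lib$conf[, 4],
                 phi3 = lib$conf[, 5], psi3 = lib$conf[, 6],
                 omega_flags = "tt", source_id = "bulk", chain = "A",
                 start = seq_len(nrow(lib$conf)),
                 stringsAsFactors = FALSE)
    }))))
  tgt <- data.frame(phi = phi, psi = psi)
  nr <- nearest_db_state(spec, db_plus, tgt)
  expect_equal(unname(nr$dist), rep(0, 8))
  expect_true(attr(nr$consistency, "ok"))
  expect_equal(chain_angles_from_state(spec, db_plus, nr$state)$phi, phi,
               tolerance = 1e-12)
  # random target: per-variable minimiser agrees with a brute-force scan
  tgt <- data.frame(phi = runif(10, -pi, pi), psi = runif(10, -pi, pi))
  nr <- nearest_db_state(spec, db, tgt, repair_slack = 0)
  for (i in seq_along(spec$keys)) {
    lib <- query_conformations(db, spec$keys[i])
    w <- as.numeric(rbind(tgt$phi[i:(i + 2)], tgt$psi[i:(i + 2)]))
    dd <- apply(lib$conf, 1, function(v) angular_rmsd(v, w))
    expect_equal(dd[nr$state[i]], min(dd), tolerance = 1e-12)
  }
})

test_that("state_rmsd: symmetry, zero on identity, hand-checked single flip", {
  db <- index_database(mini_chignolin_db(15, seed = 7))
  spec <- decompose_sequence("GYDPETGTWG")
  set.seed(66)
  for (rep in 1:10) {
    s1 <- vapply(spec$keys, function(k)
      sample.int(nrow(query_conformations(db, k)$conf), 1), integer(1))
    s2 <- vapply(spec$keys, function(k)
      sample.int(nrow(query_conformations(db, k)$conf), 1), integer(1))
    expect_equal(state_rmsd(spec, db, s1, s2), state_rmsd(spec, db, s2, s1))
    expect_gte(state_rmsd(spec, db, s1, s2), 0)
  }
  # a single residue differing by exactly pi in phi: sqrt(pi^2 / m), m = 2n
  seqc <- c("A", "C", "A")
  spc <- decompose_sequence(seqc)
  recs <- do.call(rbind, lapply(1:2, function(v)
    data.frame(key = "ACA",
               phi1 = 0, psi1 = 0,
               phi2 = if (v == 2) pi else 0, psi2 = 0,
               phi3 = 0, psi3 = 0,
               omega_flags = "tt", source_id = "x", chain = "A", start = v,
               stringsAsFactors = FALSE)))
  dbx <- build_database(recs)
  expect_equal(state_rmsd(spc, dbx, 1L, 2L), sqrt(pi^2 / 6),
               tolerance = 1e-12)
})
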