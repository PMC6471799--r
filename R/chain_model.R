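# A protein as a sequence of overlapping tripeptide state variables:
# decomposition, state assembly into full-chain dihedrals, overlap
# consistency, search-space size, nearest database state, whole-chain
# angular RMSD.

#' Decompose a sequence into overlapping tripeptide state variables
#'
#' A protein of n residues defines n - 2 state variables; variable i is the
#' tripeptide covering residues i, i+1, i+2, so consecutive variables share
#' two residues.
#'
#' @param sequence one-letter residue string (e.g. `"GYDPETGTWG"`) or
#'   character vector of one-letter codes; n >= 3, standard residues only.
#' @return object of class `protein_spec`: list with `sequence` (character
#'   vector), `n`, `keys` (character vector of n - 2 tripeptide keys).
#' @export
#' @examples
#' decompose_sequence("GYDPETGTWG")$keys  # Chignolin: 8 variables
decompose_sequence <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  n <- length(sequence)
  if (n < 3) stop("need at least 3 residues, got ", n)
  bad <- !(sequence %in% AA1)
  if (any(bad))
    stop("non-standard residue code(s): ",
         paste(unique(sequence[bad]), collapse = ", "))
  keys <- vapply(seq_len(n - 2), function(i)
    paste(sequence[i:(i + 2)], collapse = ""), character(1))
  structure(list(sequence = sequence, n = n, keys = keys),
            class = "protein_spec")
}

#' @export
print.protein_spec <- function(x, ...) {
  cat(sprintf("Protein spec: %d residues (%s), %d state variables\n",
              x$n, paste(x$sequence, collapse = ""), length(x$keys)))
  invisible(x)
}

spec_libraries <- function(spec, db) {
  libs <- lapply(spec$keys, function(k) {
    lib <- query_conformations(db, k)
    if (is.null(lib) || nrow(lib$conf) == 0)
      stop("empty domain for tripeptide key ", k)
    lib
  })
  names(libs) <- NULL
  libs
}

#' Full-chain dihedrals of a state assignment
#'
#' Each residue takes its (phi, psi) from the state variable in which it is
#' central (residue j from variable j - 1); the first residue comes from
#' variable 1 position 1 and the last from variable n - 2 position 3. For a
#' state sliced from one contiguous source chain this reproduces the source
#' angles exactly; for mixed database values the overlapping copies of a
#' shared angle disagree within the consistency tolerance and the central
#' copy is the representative.
#'
#' @param spec a [decompose_sequence()] result.
#' @param db a `tripeptide_db` covering all keys of `spec`.
#' @param s integer vector, one conformation index per state variable.
#' @return data frame with `phi`, `psi` (radians), one row per residue.
#' @export
chain_angles_from_state <- function(spec, db, s) {
  libs <- spec_libraries(spec, db)
  nv <- length(spec$keys)
  stopifnot(length(s) == nv, all(s >= 1),
            all(s <= vapply(libs, function(l) nrow(l$conf), integer(1))))
  n <- spec$n
  phi <- psi <- numeric(n)
  phi[1] <- libs[[1]]$conf[s[1], "phi1"]
  psi[1] <- libs[[1]]$conf[s[1], "psi1"]
  for (j in 2:(n - 1)) {
    phi[j] <- libs[[j - 1]]$conf[s[j - 1], "phi2"]
    psi[j] <- libs[[j - 1]]$conf[s[j - 1], "psi2"]
  }
  phi[n] <- libs[[nv]]$conf[s[nv], "phi3"]
  psi[n] <- libs[[nv]]$conf[s[nv], "psi3"]
  data.frame(phi = phi, psi = psi)
}

#' Overlap consistency of a state assignment
#'
#' Consecutive state variables share two residues, hence four dihedrals
#' (phi and psi of each shared residue). A state is consistent at tolerance
#' `eps` when every wrapped absolute difference between the two copies of a
#' shared angle is below `eps`.
#'
#' @inheritParams chain_angles_from_state
#' @param eps tolerance in radians.
#' @return data frame with one row per overlap (`var_left`, `max_violation`,
#'   `ok`); attribute `ok` gives the overall verdict.
#' @export
check_overlap_consistency <- function(spec, db, s, eps) {
  libs <- spec_libraries(spec, db)
  nv <- length(spec$keys)
  out <- data.frame(var_left = integer(0), max_violation = numeric(0),
                    ok = logical(0))
  for (i in seq_len(nv - 1)) {
    a <- libs[[i]]$conf[s[i], ]
    b <- libs[[i + 1]]$conf[s[i + 1], ]
    viol <- max(angle_diff(a["phi2"], b["phi1"]),
                angle_diff(a["psi2"], b["psi1"]),
                angle_diff(a["phi3"], b["phi2"]),
                angle_diff(a["psi3"], b["psi2"]))
    out <- rbind(out, data.frame(var_left = i, max_violation = viol,
                                 ok = viol < eps))
  }
  attr(out, "ok") <- all(out$ok)
  out
}

# --- exact big-integer product ----------------------------------------------
# Search-space sizes overflow doubles (~4e23 for a 10-residue peptide), so
# the product is carried exactly in base-1e4 digit vectors.

big_mul_scalar <- function(x, m) {
  # x: little-endian base-1e4 digits; m: non-negative integer-valued double
  if (m == 0) return(0)
  out <- numeric(0)
  shift <- 0
  while (m > 0) {
    chunk <- m %% 1e4
    m <- m %/% 1e4
    if (chunk > 0) {
      part <- c(rep(0, shift), x * chunk)
      out <- big_add(out, part)
    }
    shift <- shift + 1
  }
  # carry propagation
  carry <- 0
  for (i in seq_along(out)) {
    t <- out[i] + carry
    out[i] <- t %% 1e4
    carry <- t %/% 1e4
  }
  while (carry > 0) {
    out <- c(out, carry %% 1e4)
    carry <- carry %/% 1e4
  }
  while (length(out) > 1 && out[length(out)] == 0)
    out <- out[-length(out)]
  out
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  a + b
}

big_to_string <- function(x) {
  n <- length(x)
  paste0(format(x[n], scientific = FALSE),
         paste(sprintf("%04d", rev(x[-n])), collapse = ""))
}

#' Size of the discrete search space
#'
#' The exact product of the per-variable domain sizes, an upper bound on
#' the number of states the search could visit.
#'
#' @inheritParams chain_angles_from_state
#' @return list with `size` (exact decimal string), `log10` (numeric),
#'   `counts` (per-variable domain sizes).
#' @export
#' @examples
#' # Chignolin with the published per-tripeptide counts: ~4e23 states
search_space_size <- function(spec, db) {
  libs <- spec_libraries(spec, db)
  counts <- vapply(libs, function(l) nrow(l$conf), integer(1))
  x <- 1
  for (m in counts) x <- big_mul_scalar(x, m)
  list(size = big_to_string(x), log10 = sum(log10(counts)), counts = counts)
}

#' Nearest database state to a target conformation
#'
#' Per variable, the domain conformation minimising the angular RMSD to the
#' target's corresponding six-angle window (ties broken by lowest index).
#' Because variables are chosen independently the result can be
#' overlap-inconsistent; a greedy left-to-right repair pass then reselects,
#' among near-minimal candidates (within `repair_slack` of the minimum),
#' the lowest-distance value consistent with the already-fixed left
#' neighbour at tolerance `eps`, keeping the plain minimiser when no such
#' candidate exists.
#'
#' @inheritParams chain_angles_from_state
#' @param target data frame with `phi`, `psi` per residue (radians);
#'   terminal `NA` angles are ignored in the per-window distance.
#' @param eps overlap tolerance used by the repair pass (radians).
#' @param repair_slack distance slack defining near-minimal candidates
#'   (radians).
#' @return list with `state` (integer vector), `dist` (per-variable angular
#'   RMSD to the target window), `consistency` (the
#'   [check_overlap_consistency()] report at `eps`).
#' @export
nearest_db_state <- function(spec, db, target, eps = 0.35,
                             repair_slack = 0.35) {
  libs <- spec_libraries(spec, db)
  nv <- length(spec$keys)
  stopifnot(nrow(target) == spec$n)
  win <- function(i) {
    idx <- i:(i + 2)
    as.numeric(rbind(target$phi[idx], target$psi[idx]))
  }
  dist_to <- function(lib, w) {
    def <- !is.na(w)
    diffs <- angle_diff(lib$conf[, def, drop = FALSE],
                        matrix(w[def], nrow(lib$conf), sum(def),
                               byrow = TRUE))
    sqrt(rowMeans(diffs^2))
  }
  dists <- lapply(seq_len(nv), function(i) dist_to(libs[[i]], win(i)))
  state <- vapply(dists, which.min, integer(1))
  # greedy repair
  for (i in seq_len(nv)[-1]) {
    a <- libs[[i - 1]]$conf[state[i - 1], ]
    di <- dists[[i]]
    cand <- which(di <= min(di) + repair_slack)
    cand <- cand[order(di[cand], cand)]
    consistent <- function(v) {
      b <- libs[[i]]$conf[v, ]
      max(angle_diff(a["phi2"], b["phi1"]), angle_diff(a["psi2"], b["psi1"]),
          angle_diff(a["phi3"], b["phi2"]),
          angle_diff(a["psi3"], b["psi2"])) < eps
    }
    ok <- cand[vapply(cand, consistent, logical(1))]
    state[i] <- if (length(ok)) ok[1] else which.min(di)
  }
  best <- vapply(seq_len(nv), function(i) dists[[i]][state[i]], numeric(1))
  list(state = state, dist = best,
       consistency = check_overlap_consistency(spec, db, state, eps))
}

#' Whole-chain angular RMSD between two states
#'
#' Root-mean-square of the wrapped differences over the full-chain dihedral
#' lists extracted by [chain_angles_from_state()] (all 2n angles: database
#' conformations carry defined values for every position).
#'
#' @inheritParams chain_angles_from_state
#' @param s1,s2 state assignments.
#' @return distance in radians; 0 iff the extracted angle lists coincide.
#' @export
state_rmsd <- function(spec, db, s1, s2) {
  a <- chain_angles_from_state(spec, db, s1)
  b <- chain_angles_from_state(spec, db, s2)
  d <- angle_diff(c(a$phi, a$psi), c(b$phi, b$psi))
  def <- !is.na(d)
  sqrt(mean(d[def]^2))
}

#' Cartesian chain of a state assignment
#'
#' Convenience composition: extract full-chain dihedrals and reconstruct
#' backbone coordinates under rigid geometry.
#'
#' @inheritParams chain_angles_from_state
#' @param geom a [rigid_geometry()].
#' @return a `chain_coords` object.
#' @export
chain_from_state <- function(spec, db, s, geom = rigid_geometry()) {
  ang <- chain_angles_from_state(spec, db, s)
  reconstruct_backbone(spec$sequence, ang, geom)
}
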