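# Steric feasibility of assembled chains. A pair of non-bonded
# (pseudo-)atoms collides when their distance is below overlap_factor times
# the sum of their radii (default 65%). The broad phase is a cell
# linked-list; its report is exactly the naive all-pairs scan's.

#' Read a two-column radii table
#'
#' @param path text file: one-letter residue code, radius in Angstrom,
#'   tab- or space-separated; `#` comments allowed.
#' @return named numeric vector of radii.
#' @export
read_radii_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("code", "radius"),
                           stringsAsFactors = FALSE)
  stats::setNames(tab$radius, tab$code)
}

#' Collision model: radii, overlap factor, bonded exclusions
#'
#' Backbone atoms carry van der Waals radii (Bondi: N 1.55, C 1.70,
#' O 1.52 Angstrom); each side chain is one pseudo-atom at the beta-carbon
#' with a per-residue radius from the shipped table. Atom pairs separated
#' by up to `exclusion_depth` covalent bonds are exempt (the pseudo-atom
#' counts as bonded to its CA).
#'
#' @param overlap_factor collision threshold as a fraction of the radii sum
#'   (default 0.65).
#' @param exclusion_depth bonded-separation cutoff in bonds (default 3,
#'   i.e. 1-2, 1-3 and 1-4 pairs are exempt).
#' @param backbone_radii named numeric vector with entries `N`, `C`, `O`
#'   (CA and carbonyl C share the carbon radius).
#' @param pseudo_radii named numeric vector of per-residue pseudo-atom
#'   radii; defaults to the packaged table.
#' @param pseudo_radii_file optional path to an alternative radii table.
#' @return object of class `collision_model`.
#' @export
collision_model <- function(overlap_factor = 0.65, exclusion_depth = 3,
                            backbone_radii = c(N = 1.55, C = 1.70, O = 1.52),
                            pseudo_radii = NULL,
                            pseudo_radii_file = NULL) {
  stopifnot(overlap_factor > 0, overlap_factor < 1, exclusion_depth >= 0)
  if (is.null(pseudo_radii)) {
    if (is.null(pseudo_radii_file))
      pseudo_radii_file <- system.file("extdata", "pseudo_atom_radii.tsv",
                                       package = "tripath", mustWork = TRUE)
    pseudo_radii <- read_radii_table(pseudo_radii_file)
  }
  stopifnot(all(backbone_radii > 0), all(pseudo_radii > 0))
  structure(list(overlap_factor = overlap_factor,
                 exclusion_depth = exclusion_depth,
                 backbone_radii = backbone_radii,
                 pseudo_radii = pseudo_radii),
            class = "collision_model")
}

# Flatten a chain_coords into an atom table and bond list. Atom order per
# residue: N, CA, C, O, CB (5 atoms per residue). The topology (bonds,
# exclusion mask, radii) depends only on the sequence and exclusion depth,
# so it is cached across calls — collision checks run once per candidate
# transition in the search inner loop.
.layout_cache <- new.env(hash = TRUE, parent = emptyenv())

chain_layout <- function(sequence, model) {
  key <- paste(paste(sequence, collapse = ""), model$exclusion_depth,
               paste(model$backbone_radii, collapse = ","),
               sum(model$pseudo_radii), sep = "|")
  hit <- .layout_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(sequence)
  unknown <- setdiff(sequence, names(model$pseudo_radii))
  if (length(unknown) > 0)
    stop("no pseudo-atom radius for residue type: ",
         paste(unknown, collapse = ", "))
  radius <- as.numeric(rbind(model$backbone_radii["N"],
                             model$backbone_radii["C"],
                             model$backbone_radii["C"],
                             model$backbone_radii["O"],
                             model$pseudo_radii[sequence]))
  o <- (seq_len(n) - 1) * 5
  bonds <- rbind(cbind(o + 1, o + 2),  # N-CA
                 cbind(o + 2, o + 3),  # CA-C
                 cbind(o + 3, o + 4),  # C-O
                 cbind(o + 2, o + 5))  # CA-CB (pseudo-atom bonded to CA)
  if (n > 1) bonds <- rbind(bonds, cbind(o[-n] + 3, o[-1] + 1)) # C-N(k+1)
  excl <- excluded_matrix(5L * n, bonds, model$exclusion_depth)
  layout <- list(n_atoms = 5L * n, radius = radius, bonds = bonds,
                 excl = excl,
                 thr = model$overlap_factor * outer(radius, radius, "+"))
  .layout_cache[[key]] <- layout
  layout
}

chain_xyz <- function(chain) {
  n <- nrow(chain$CA)
  xyz <- matrix(NA_real_, 5 * n, 3)
  idx <- (seq_len(n) - 1) * 5
  xyz[idx + 1, ] <- chain$N
  xyz[idx + 2, ] <- chain$CA
  xyz[idx + 3, ] <- chain$C
  xyz[idx + 4, ] <- chain$O
  xyz[idx + 5, ] <- chain$CB
  xyz
}

# logical matrix marking atom pairs within `depth` covalent bonds
excluded_matrix <- function(n_atoms, bonds, depth) {
  adj <- vector("list", n_atoms)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1]; b <- bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  excl <- diag(TRUE, n_atoms)
  for (start in seq_len(n_atoms)) {
    dist <- rep(NA_integer_, n_atoms)
    dist[start] <- 0L
    frontier <- start
    for (step in seq_len(depth)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (length(nxt) == 0) break
      dist[nxt] <- step
      frontier <- nxt
    }
    excl[start, !is.na(dist)] <- TRUE
  }
  excl | t(excl)
}

#' Detect steric collisions in an assembled chain
#'
#' Reports every non-excluded atom pair closer than
#' `overlap_factor * (r_i + r_j)`. `method = "cell"` uses a cell linked-list
#' broad phase (cell edge = the largest collision threshold over atom
#' pairs); `method = "naive"` scans all pairs. Both return identical
#' reports.
#'
#' @param chain a `chain_coords` object.
#' @param model a [collision_model()].
#' @param method `"auto"` (default; cell list above 150 atoms, where the
#'   broad phase starts to pay for its bookkeeping, vectorised all-pairs
#'   below), `"cell"`, or `"naive"`.
#' @return list with `collision` (logical), `pairs` (m-by-2 matrix of
#'   offending atom indices, ordered), `n_atoms`.
#' @export
detect_collisions <- function(chain, model = collision_model(),
                              method = c("auto", "cell", "naive")) {
  method <- match.arg(method)
  lay <- chain_layout(chain$sequence, model)
  xyz <- chain_xyz(chain)
  n <- lay$n_atoms
  if (method == "auto") method <- if (n > 150) "cell" else "naive"
  hits <- NULL
  if (method == "naive") {
    d2 <- as.matrix(stats::dist(xyz))^2
    hit <- d2 < lay$thr^2 & !lay$excl
    hit[!upper.tri(hit)] <- FALSE
    idx <- which(hit, arr.ind = TRUE)
    hits <- idx
  } else {
    # cell linked-list broad phase: cell edge = largest collision threshold
    cell <- model$overlap_factor * 2 * max(lay$radius)
    ci <- floor(xyz / cell)
    keys <- paste(ci[, 1], ci[, 2], ci[, 3])
    buckets <- split(seq_len(n), keys)
    offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    acc <- vector("list", n)
    for (i in seq_len(n)) {
      neigh_keys <- paste(ci[i, 1] + offsets[, 1],
                          ci[i, 2] + offsets[, 2],
                          ci[i, 3] + offsets[, 3])
      cand <- unlist(buckets[neigh_keys], use.names = FALSE)
      cand <- cand[cand > i]
      cand <- cand[!lay$excl[i, cand]]
      if (length(cand) == 0) next
      dd <- xyz[cand, , drop = FALSE] -
        matrix(xyz[i, ], length(cand), 3, byrow = TRUE)
      close <- cand[rowSums(dd * dd) < lay$thr[i, cand]^2]
      if (length(close) > 0) acc[[i]] <- cbind(i, close)
    }
    hits <- do.call(rbind, acc)
  }
  if (is.null(hits) || nrow(hits) == 0) {
    hits <- matrix(0L, 0, 2)
  } else {
    hits <- matrix(as.integer(hits), ncol = 2)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  }
  colnames(hits) <- c("i", "j")
  list(collision = nrow(hits) > 0, pairs = hits, n_atoms = n)
}
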