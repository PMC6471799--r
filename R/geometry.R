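# Angular metrics between tripeptide conformations and conversion between
# internal coordinates (phi/psi under rigid geometry) and Cartesian backbone
# coordinates.
#
# A tripeptide conformation is a numeric vector of six backbone dihedrals,
# in order (phi1, psi1, phi2, psi2, phi3, psi3), radians in (-pi, pi].

TRIPEP_ANGLE_NAMES <- c("phi1", "psi1", "phi2", "psi2", "phi3", "psi3")

#' Construct a tripeptide conformation vector
#'
#' @param phi,psi numeric length-3, backbone dihedrals in radians for the
#'   three residues of the fragment.
#' @return named numeric length-6 vector `(phi1, psi1, ..., psi3)`, wrapped
#'   into `(-pi, pi]`.
#' @export
tripeptide_conformation <- function(phi, psi) {
  stopifnot(length(phi) == 3, length(psi) == 3,
            all(is.finite(phi)), all(is.finite(psi)))
  v <- wrap_angle(as.numeric(rbind(phi, psi)))
  names(v) <- TRIPEP_ANGLE_NAMES
  v
}

as_conf_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 6)
    x
  } else {
    matrix(as.numeric(x), ncol = 6, byrow = TRUE,
           dimnames = list(NULL, TRIPEP_ANGLE_NAMES))
  }
}

#' Angular RMSD between two tripeptide conformations
#'
#' Root-mean-square of the six wrapped dihedral differences,
#' `sqrt(1/6 * sum(dphi_j^2 + dpsi_j^2))`. Differences are taken along the
#' shorter arc so the metric is continuous on the torus.
#'
#' @param a,b numeric length-6 conformation vectors (see
#'   [tripeptide_conformation()]).
#' @return distance in radians, in `[0, pi]`.
#' @export
angular_rmsd <- function(a, b) {
  stopifnot(length(a) == 6, length(b) == 6)
  d <- angle_diff(a, b)
  sqrt(mean(d^2))
}

#' Central distance between two tripeptide conformations
#'
#' The same angular RMSD restricted to the central residue's (phi, psi).
#' With `norm = "per-angle"` (default) the mean runs over the two angles
#' considered, so the value is an RMSD in its own right; `norm =
#' "one-sixth"` keeps the full six-angle normalisation.
#'
#' @inheritParams angular_rmsd
#' @param norm normalisation convention, `"per-angle"` or `"one-sixth"`.
#' @return distance in radians.
#' @export
central_distance <- function(a, b, norm = c("per-angle", "one-sixth")) {
  norm <- match.arg(norm)
  stopifnot(length(a) == 6, length(b) == 6)
  d <- angle_diff(a[3:4], b[3:4])
  if (norm == "per-angle") sqrt(mean(d^2)) else sqrt(sum(d^2) / 6)
}

#' Rigid backbone geometry constants
#'
#' Canonical bond lengths (Angstrom) and bond angles (radians) used for
#' internal-to-Cartesian reconstruction; only phi/psi remain variable, the
#' peptide torsion omega is fixed at pi (trans).
#'
#' @param b_n_ca,b_ca_c,b_c_n,b_c_o,b_ca_cb bond lengths in Angstrom.
#' @param a_n_ca_c,a_ca_c_n,a_c_n_ca,a_ca_c_o,a_n_ca_cb bond angles in
#'   radians.
#' @param omega fixed peptide-bond torsion in radians (trans = pi).
#' @return an object of class `rigid_geometry` (a named list).
#' @export
rigid_geometry <- function(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                           b_c_o = 1.231, b_ca_cb = 1.521,
                           a_n_ca_c = 111.2 * pi / 180,
                           a_ca_c_n = 116.2 * pi / 180,
                           a_c_n_ca = 121.7 * pi / 180,
                           a_ca_c_o = 120.8 * pi / 180,
                           a_n_ca_cb = 110.5 * pi / 180,
                           omega = pi) {
  g <- list(b_n_ca = b_n_ca, b_ca_c = b_ca_c, b_c_n = b_c_n, b_c_o = b_c_o,
            b_ca_cb = b_ca_cb, a_n_ca_c = a_n_ca_c, a_ca_c_n = a_ca_c_n,
            a_c_n_ca = a_c_n_ca, a_ca_c_o = a_ca_c_o,
            a_n_ca_cb = a_n_ca_cb, omega = omega)
  stopifnot(all(vapply(g, is.numeric, logical(1))),
            b_n_ca > 0, b_ca_c > 0, b_c_n > 0, b_c_o > 0, b_ca_cb > 0)
  structure(g, class = "rigid_geometry")
}

# NeRF atom placement: position of D bonded to C, with bond length r,
# bond angle B-C-D = ang and torsion A-B-C-D = tor.
place_atom <- function(a, b, c_, r, ang, tor) {
  bc <- c_ - b
  bc <- bc / sqrt(sum(bc * bc))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n * n))
  m <- cross3(n, bc)
  d2 <- r * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c_ + bc * d2[1] + m * d2[2] + n * d2[3]
}

#' Assemble backbone Cartesian coordinates from dihedrals
#'
#' Sequential natural-extension (NeRF) placement under rigid geometry: bond
#' lengths, bond angles and the peptide torsion omega are fixed at the
#' `geom` constants, phi/psi are taken from `angles`. The carbonyl oxygen
#' and one side-chain pseudo-atom per residue (centred at the beta-carbon
#' position; a virtual site for glycine) are placed by fixed local geometry.
#'
#' phi of residue 1 and psi of the last residue do not affect the backbone
#' and may be `NA`; psi of the last residue only orients its carbonyl
#' oxygen, for which a trans convention is used when it is `NA`.
#'
#' @param sequence character vector of one-letter residue codes, length n.
#' @param angles data frame or list with numeric `phi` and `psi` of length
#'   n (radians).
#' @param geom a [rigid_geometry()] object.
#' @return an object of class `chain_coords`: list with `sequence` and
#'   n-by-3 matrices `N`, `CA`, `C`, `O`, `CB`.
#' @export
reconstruct_backbone <- function(sequence, angles, geom = rigid_geometry()) {
  n <- length(sequence)
  phi <- as.numeric(angles$phi)
  psi <- as.numeric(angles$psi)
  stopifnot(n >= 1, length(phi) == n, length(psi) == n)
  if (anyNA(phi[-1]) || anyNA(psi[-n]))
    stop("NA in an interior phi/psi angle")
  if (any(is.nan(c(phi[-1], psi[-n]))))
    stop("NaN angle rejected")

  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(geom$b_n_ca, 0, 0)
  C[1, ] <- CA[1, ] + geom$b_ca_c *
    c(-cos(geom$a_n_ca_c), sin(geom$a_n_ca_c), 0)
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      N[k + 1, ] <- place_atom(N[k, ], CA[k, ], C[k, ],
                               geom$b_c_n, geom$a_ca_c_n, psi[k])
      CA[k + 1, ] <- place_atom(CA[k, ], C[k, ], N[k + 1, ],
                                geom$b_n_ca, geom$a_c_n_ca, geom$omega)
      C[k + 1, ] <- place_atom(C[k, ], N[k + 1, ], CA[k + 1, ],
                               geom$b_ca_c, geom$a_n_ca_c, phi[k + 1])
    }
  }
  for (k in seq_len(n)) {
    # carbonyl O trans to the next amide N (torsion N-CA-C-O = psi + pi)
    tor_o <- if (k < n) wrap_angle(psi[k] + pi) else
      if (is.na(psi[k])) pi else wrap_angle(psi[k] + pi)
    O[k, ] <- place_atom(N[k, ], CA[k, ], C[k, ],
                         geom$b_c_o, geom$a_ca_c_o, tor_o)
    # beta-carbon pseudo-atom; fixed improper torsion C-N-CA-CB sets the
    # L-configuration side of the backbone plane
    CB[k, ] <- place_atom(C[k, ], N[k, ], CA[k, ],
                          geom$b_ca_cb, geom$a_n_ca_cb,
                          -122.6 * pi / 180)
  }
  structure(list(sequence = sequence, N = N, CA = CA, C = C, O = O, CB = CB),
            class = "chain_coords")
}

#' Backbone dihedrals of a Cartesian chain
#'
#' Standard four-atom torsions: phi(k) from (C[k-1], N[k], CA[k], C[k]),
#' psi(k) from (N[k], CA[k], C[k], N[k+1]), omega(k) (peptide bond k to
#' k+1) from (CA[k], C[k], N[k+1], CA[k+1]). Terminal phi[1] and psi[n]
#' (and omega[n]) are undefined and returned as `NA`, never fabricated.
#'
#' @param chain a `chain_coords` object, or any list with n-by-3 `N`, `CA`,
#'   `C` matrices.
#' @return data frame with columns `phi`, `psi`, `omega` (radians, wrapped
#'   to `(-pi, pi]`), one row per residue; `NA` where undefined or where a
#'   backbone atom is missing.
#' @export
compute_dihedrals <- function(chain) {
  N <- chain$N; CA <- chain$CA; C <- chain$C
  n <- nrow(CA)
  phi <- psi <- omega <- rep(NA_real_, n)
  ok <- function(m, k) k >= 1 && k <= n && all(is.finite(m[k, ]))
  for (k in seq_len(n)) {
    if (k > 1 && ok(C, k - 1) && ok(N, k) && ok(CA, k) && ok(C, k))
      phi[k] <- torsion_angle(C[k - 1, ], N[k, ], CA[k, ], C[k, ])
    if (k < n && ok(N, k) && ok(CA, k) && ok(C, k) && ok(N, k + 1))
      psi[k] <- torsion_angle(N[k, ], CA[k, ], C[k, ], N[k + 1, ])
    if (k < n && ok(CA, k) && ok(C, k) && ok(N, k + 1) && ok(CA, k + 1))
      omega[k] <- torsion_angle(CA[k, ], C[k, ], N[k + 1, ], CA[k + 1, ])
  }
  data.frame(phi = phi, psi = psi, omega = omega)
}
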