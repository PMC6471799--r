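# Angle arithmetic on the torus. All internal angles are radians wrapped
# into (-pi, pi].

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles mapped to the canonical representative in `(-pi, pi]`.
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi))
wrap_angle <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Minimal angular difference
#'
#' Absolute difference between two angles measured along the shorter arc of
#' the circle; always in `[0, pi]`.
#'
#' @param a,b numeric vectors of angles in radians.
#' @return non-negative numeric vector of minimal differences.
#' @export
angle_diff <- function(a, b) {
  abs(wrap_angle(a - b))
}

#' Torsion angle of four points
#'
#' Signed dihedral about the `p2`-`p3` axis under the IUPAC convention:
#' 0 for an eclipsed (cis) arrangement, pi for trans, positive for a
#' clockwise rotation of `p4` relative to `p1` looking from `p2` to `p3`.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors.
#' @return torsion in radians, wrapped to `(-pi, pi]`; `NA` if any two of
#'   the defining bond vectors are (anti)parallel.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p1 - p2
  b2 <- p3 - p2
  b3 <- p4 - p3
  n2 <- sqrt(sum(b2 * b2))
  if (n2 == 0) return(NA_real_)
  b2u <- b2 / n2
  # component of b1/b3 orthogonal to the rotation axis
  v <- b1 - sum(b1 * b2u) * b2u
  w <- b3 - sum(b3 * b2u) * b2u
  nv <- sqrt(sum(v * v))
  nw <- sqrt(sum(w * w))
  if (nv < 1e-12 || nw < 1e-12) return(NA_real_)
  x <- sum(v * w)
  y <- sum(cross3(b2u, v) * w)
  wrap_angle(atan2(y, x))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
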