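#' Angle wrapping helpers
#'
#' `wrap180()` maps angles into the torsion reporting range (-180, 180];
#' `wrap360()` maps into [0, 360), the range used for the pseudorotation
#' phase.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of wrapped angles in degrees.
#' @export
wrap180 <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

#' @rdname wrap180
#' @export
wrap360 <- function(x) {
  x %% 360
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(u, v) {
  cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
}

as_mat3 <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

#' Dihedral angle of four points
#'
#' Computes the signed torsion angle defined by four points, row-wise over
#' four n x 3 coordinate matrices (or single length-3 vectors). The sign
#' follows the convention of the standard structural-biology toolkits
#' (IUPAC): looking from `b` towards `c`, the angle is the rotation of the
#' far bond `c`-`d` relative to the near bond `b`-`a`, with the
#' trans/antiperiplanar arrangement at 180 degrees.
#'
#' Degenerate input (coincident `b`, `c`, or collinear triples, or any
#' missing coordinate) yields `NA` rather than an error: one bad residue
#' must never abort a whole-structure run.
#'
#' @param a,b,c,d length-3 numeric vectors or n x 3 matrices of coordinates
#'   in Angstroms.
#' @return numeric vector of angles in degrees in (-180, 180], `NA` where
#'   undefined.
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)) # trans: 180
#' @export
dihedral <- function(a, b, c, d) {
  a <- as_mat3(a); b <- as_mat3(b); c <- as_mat3(c); d <- as_mat3(d)
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  b2len <- sqrt(rowSums(b2^2))
  # y/x components of the two-argument arctangent (no quadrant loss)
  x <- rowSums(n1 * n2)
  y <- rowSums(cross3(n1, n2) * (b2 / b2len))
  ang <- rad2deg(atan2(y, x))
  n1len2 <- rowSums(n1^2)
  n2len2 <- rowSums(n2^2)
  bad <- !is.finite(b2len) | b2len < 1e-9 | !is.finite(n1len2) |
    !is.finite(n2len2) | n1len2 < 1e-18 | n2len2 < 1e-18
  ang[bad] <- NA_real_
  unname(wrap180(ang))
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF) placement: given three reference positions
#' `a`, `b`, `c`, returns the position `d` bonded to `c` with bond length
#' `r`, bond angle `b`-`c`-`d` equal to `theta`, and dihedral
#' `a`-`b`-`c`-`d` equal to `phi` under the same sign convention as
#' [dihedral()].
#'
#' @param a,b,c length-3 numeric coordinate vectors.
#' @param r bond length `c`-`d` in Angstroms.
#' @param theta bond angle `b`-`c`-`d` in degrees.
#' @param phi dihedral `a`-`b`-`c`-`d` in degrees.
#' @return length-3 numeric coordinate vector.
#' @export
place_atom <- function(a, b, c, r, theta, phi) {
  th <- deg2rad(theta)
  ph <- deg2rad(phi)
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / sqrt(sum(n^2))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  d2 <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Bond angle a-b-c in degrees (row-wise).
bond_angle <- function(a, b, c) {
  a <- as_mat3(a); b <- as_mat3(b); c <- as_mat3(c)
  u <- a - b
  v <- c - b
  cosang <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}
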