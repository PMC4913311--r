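# Internal-coordinate geometry: torsions and atom placement.

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return torsion angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D bonded to C with |CD| = bond, angle B-C-D = theta (degrees) and
# torsion A-B-C-D = chi (degrees).  Natural-extension reference frame.
.place_atom <- function(a, b, c, bond, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ch),
          -bond * sin(th) * sin(ch))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(rot %*% d2 + c)
}

# absolute angular difference wrapped to [0, 180]
.wrap_delta <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}
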