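# Small numerical helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) stop("logsumexp: non-finite input")
  m + log(sum(exp(x - m)))
}

#' Dihedral angle of four points
#'
#' Signed torsion angle, in degrees in (-180, 180], of the quadruplet
#' p1-p2-p3-p4 about the p2-p3 axis.  Uses the atan2 formulation, which is
#' stable near 0 and 180 degrees.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(b2 / sqrt(sum(b2^2)), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  # map -180 to +180 so the range is (-180, 180]
  if (isTRUE(all.equal(ang, -180, tolerance = 1e-12))) ang <- 180
  ang
}

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @keywords internal
rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c0 <- cos(th); s0 <- sin(th); C <- 1 - c0
  matrix(c(
    c0 + a[1]^2 * C,        a[1] * a[2] * C - a[3] * s0, a[1] * a[3] * C + a[2] * s0,
    a[2] * a[1] * C + a[3] * s0, c0 + a[2]^2 * C,        a[2] * a[3] * C - a[1] * s0,
    a[3] * a[1] * C - a[2] * s0, a[3] * a[2] * C + a[1] * s0, c0 + a[3]^2 * C),
    nrow = 3, byrow = TRUE)
}

# Boltzmann constant in kJ/(mol K), used for bias-potential reweighting.
KB_KJ_MOL <- 0.00831446261815324
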