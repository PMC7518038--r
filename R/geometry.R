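# Small 3D geometry toolkit used by derivatization, minimization and the
# synthetic builder. All functions operate on plain numeric vectors/matrices;
# coordinates are in Angstrom.

vecNorm <- function(v) sqrt(sum(v * v))

unitVec <- function(v) {
  n <- vecNorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' Rotation matrix about an arbitrary axis (Rodrigues)
#'
#' @param axis 3-vector, need not be normalized.
#' @param theta rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotationMatrix <- function(axis, theta) {
  u <- unitVec(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * tcrossprod(u)
}

# Rotation taking unit direction a onto unit direction b (minimal rotation).
alignRotation <- function(a, b) {
  a <- unitVec(a); b <- unitVec(b)
  v <- c(a[2L] * b[3L] - a[3L] * b[2L],
         a[3L] * b[1L] - a[1L] * b[3L],
         a[1L] * b[2L] - a[2L] * b[1L])
  s <- vecNorm(v)
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3L))
    # antiparallel: rotate pi about any axis perpendicular to a
    perp <- crossProd(a, pickPerpendicular(a))
    return(rotationMatrix(perp, pi))
  }
  rotationMatrix(v, atan2(s, cth))
}

crossProd <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# A deterministic vector not parallel to v (global axis least aligned with v).
pickPerpendicular <- function(v) {
  ax <- diag(3L)[, which.min(abs(v)), drop = TRUE]
  unitVec(crossProd(v, ax))
}

# Angle a-b-c in radians.
bondAngle <- function(a, b, c) {
  u <- a - b; v <- c - b
  ct <- sum(u * v) / (vecNorm(u) * vecNorm(v))
  acos(max(-1, min(1, ct)))
}

# Signed dihedral a-b-c-d in radians, IUPAC convention.
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- crossProd(b1, b2)
  n2 <- crossProd(b2, b3)
  m1 <- crossProd(n1, unitVec(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Place an atom by internal coordinates (NeRF construction)
#'
#' Positions a new atom \code{d} at distance \code{r} from \code{c}, with
#' angle(b, c, d) = \code{theta} and dihedral(a, b, c, d) = \code{phi}.
#'
#' @param a,b,c 3-vectors of previously placed atoms.
#' @param r bond length (Angstrom), \code{theta}, \code{phi} in degrees.
#' @keywords internal
placeAtomZ <- function(a, b, c, r, theta, phi) {
  theta <- theta * pi / 180; phi <- phi * pi / 180
  bc <- unitVec(c - b)
  n <- unitVec(crossProd(b - a, bc))
  m <- crossProd(n, bc)
  d2 <- c(-r * cos(theta),
          r * sin(theta) * cos(phi),
          r * sin(theta) * sin(phi))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Root-mean-square deviation without superposition (fixed correspondence).
rmsdNoFit <- function(x, y) {
  if (!all(dim(x) == dim(y))) stop("coordinate sets differ in size")
  sqrt(mean(rowSums((x - y)^2)))
}

# Rigid transform applied to an n x 3 coordinate matrix.
applyRigid <- function(xyz, R = diag(3L), t = c(0, 0, 0), center = c(0, 0, 0)) {
  sweep(sweep(xyz, 2L, center) %*% t(R), 2L, center + t, "+")
}

# Least-squares plane normal of a point set (unit vector).
planeNormal <- function(xyz) {
  cc <- sweep(xyz, 2L, colMeans(xyz))
  sv <- svd(cc)
  sv$v[, 3L]
}
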