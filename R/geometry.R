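# Vector geometry: torsion angles and Kabsch least-squares superposition.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' Standard right-handed torsion convention: looking down the p2->p3 bond,
#' the angle is positive when the far bond rotates clockwise relative to the
#' near bond. Range (-180, 180] degrees; a cis (eclipsed) arrangement is 0,
#' trans is 180.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates, Angstrom.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  stopifnot(length(p1) == 3, length(p2) == 3, length(p3) == 3, length(p4) == 3)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("collinear point triplet: dihedral undefined")
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2u)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping `mov` onto `ref`, via the
#' SVD of the covariance matrix with the usual determinant correction so the
#' result is a proper rotation.
#'
#' @param ref,mov n x 3 coordinate matrices (n >= 3), matched rows.
#' @return list with `R` (3 x 3 rotation), `t` (translation), `rmsd`, and
#'   `transform(x)` applying the fit to an arbitrary m x 3 matrix.
#' @export
kabsch <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov) || ncol(ref) != 3 || ncol(mov) != 3)
    stop("'ref' and 'mov' must be matched n x 3 matrices")
  if (nrow(ref) < 3) stop("need at least 3 atoms to superpose")
  cr <- colMeans(ref); cm <- colMeans(mov)
  A <- sweep(mov, 2, cm); B <- sweep(ref, 2, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cr - as.numeric(R %*% cm)
  fit <- sweep(A %*% t(R), 2, cr, `+`)
  rmsd <- sqrt(mean(rowSums((fit - ref)^2)))
  list(R = R, t = t_vec, rmsd = rmsd,
       transform = function(x) sweep(as.matrix(x) %*% t(R), 2, t_vec, `+`))
}

#' Minimal RMSD after optimal superposition
#'
#' @param ref,mov matched n x 3 coordinate matrices (n >= 3).
#' @return RMSD in the units of the coordinates (Angstrom).
#' @export
superpose_rmsd <- function(ref, mov) kabsch(ref, mov)$rmsd
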