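# Independent oracles used by property tests: a brute-force rigid-body
# RMSD minimizer (Euler-angle optimization from random restarts, no SVD)
# and small random-geometry builders.

rot_euler <- function(p) {
  cx <- cos(p[1]); sx <- sin(p[1])
  cy <- cos(p[2]); sy <- sin(p[2])
  cz <- cos(p[3]); sz <- sin(p[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

rmsd_bruteforce <- function(ref, mov, restarts = 12) {
  A <- sweep(mov, 2, colMeans(mov))
  B <- sweep(ref, 2, colMeans(ref))
  obj <- function(p) sqrt(mean(rowSums((A %*% t(rot_euler(p)) - B)^2)))
  best <- obj(c(0, 0, 0))
  for (i in seq_len(restarts)) {
    o <- stats::optim(stats::runif(3, -pi, pi), obj,
                      control = list(maxit = 500, reltol = 1e-12))
    o <- stats::optim(o$par, obj, control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

random_rotation <- function() rot_euler(stats::runif(3, -pi, pi))

random_coords <- function(n) matrix(stats::rnorm(3 * n, sd = 2), n, 3)

.cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
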