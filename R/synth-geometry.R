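# Idealized duplex geometry for the synthetic frame generator: internal
# coordinate (NeRF) atom placement, planar base templates with correct atom
# names for A/C/G/U and the N7-linked adenosines, and constructive placement
# of the opposing middle base so a prescribed number of inter-strand
# hydrogen bonds forms. The geometry is idealized (template rings, plausible
# bond lengths), not an A-form builder: every consuming operation here is
# geometric, not energetic.

.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) stop("collinear reference atoms in placement")
  n <- n / nn
  m <- .cross3(n, bc)
  c + as.numeric(cbind(bc, m, n) %*% d2)
}

# vertices of a regular n-ring given two adjacent vertices; `side` = +1/-1
# picks which side of the p1->p2 edge the ring lies on.
.ring_vertices <- function(p1, p2, n, side = 1) {
  e <- p2 - p1
  len <- sqrt(sum(e^2))
  mid <- (p1 + p2) / 2
  perp <- c(-e[2], e[1]) / len * side
  center <- mid + perp * len / (2 * tan(pi / n))
  th1 <- atan2(p1[2] - center[2], p1[1] - center[1])
  th2 <- atan2(p2[2] - center[2], p2[1] - center[1])
  dth <- (th2 - th1) %% (2 * pi)
  step <- if (abs(dth - 2 * pi / n) < 1e-8) 2 * pi / n else -2 * pi / n
  R <- len / (2 * sin(pi / n))
  t(vapply(0:(n - 1), function(k)
    center + R * c(cos(th1 + k * step), sin(th1 + k * step)), numeric(2)))
}

.radial_sub <- function(xy, center, atom, length) {
  u <- xy[atom, ] - center
  xy[atom, ] + u / sqrt(sum(u^2)) * length
}

# planar 2D base templates; rownames are atom names. `link` is the
# glycosidic nitrogen, `partner` the chi-defining base atom.
.base_template <- function(code) {
  if (code %in% c("A", "7A", "AL", "7AL", "G")) {
    C4 <- c(0, 0); C5 <- c(1.39, 0)
    # vertices come back in walk order p1, p2, onward around the ring
    pent <- .ring_vertices(C4, C5, 5, side = 1)   # C4 C5 N7 C8 N9
    hexv <- .ring_vertices(C4, C5, 6, side = -1)  # C4 C5 C6 N1 C2 N3
    xy <- rbind(C4 = C4, C5 = C5, N7 = pent[3, ], C8 = pent[4, ],
                N9 = pent[5, ], C6 = hexv[3, ], N1 = hexv[4, ],
                C2 = hexv[5, ], N3 = hexv[6, ])
    pc <- colMeans(pent); hc <- colMeans(hexv)
    xy <- rbind(xy, H8 = .radial_sub(xy, pc, "C8", 1.08))
    if (code == "G") {
      xy <- rbind(xy,
                  O6 = .radial_sub(xy, hc, "C6", 1.23),
                  N2 = .radial_sub(xy, hc, "C2", 1.34),
                  H1 = .radial_sub(xy, hc, "N1", 1.01))
      n2 <- xy["N2", ]; u <- (n2 - xy["C2", ]); u <- u / sqrt(sum(u^2))
      rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                              sin(a) * v[1] + cos(a) * v[2])
      xy <- rbind(xy, H21 = n2 + rot(u, pi / 3) * 1.01,
                  H22 = n2 + rot(u, -pi / 3) * 1.01)
    } else {
      n6 <- .radial_sub(xy, hc, "C6", 1.34)
      xy <- rbind(xy, N6 = n6, H2 = .radial_sub(xy, hc, "C2", 1.08))
      u <- (n6 - xy["C6", ]); u <- u / sqrt(sum(u^2))
      rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                              sin(a) * v[1] + cos(a) * v[2])
      xy <- rbind(xy, H61 = n6 + rot(u, pi / 3) * 1.01,
                  H62 = n6 + rot(u, -pi / 3) * 1.01)
    }
    if (code %in% c("7A", "7AL")) list(xy = xy, link = "N7", partner = "C5")
    else list(xy = xy, link = "N9", partner = "C4")
  } else if (code %in% c("C", "U")) {
    N1 <- c(0, 0); C2 <- c(1.39, 0)
    hexv <- .ring_vertices(N1, C2, 6, side = 1)   # N1 C2 N3 C4 C5 C6
    xy <- rbind(N1 = N1, C2 = C2, N3 = hexv[3, ], C4 = hexv[4, ],
                C5 = hexv[5, ], C6 = hexv[6, ])
    hc <- colMeans(hexv)
    xy <- rbind(xy,
                O2 = .radial_sub(xy, hc, "C2", 1.23),
                H5 = .radial_sub(xy, hc, "C5", 1.08),
                H6 = .radial_sub(xy, hc, "C6", 1.08))
    if (code == "U") {
      xy <- rbind(xy, O4 = .radial_sub(xy, hc, "C4", 1.23),
                  H3 = .radial_sub(xy, hc, "N3", 1.01))
    } else {
      n4 <- .radial_sub(xy, hc, "C4", 1.34)
      xy <- rbind(xy, N4 = n4)
      u <- (n4 - xy["C4", ]); u <- u / sqrt(sum(u^2))
      rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                              sin(a) * v[1] + cos(a) * v[2])
      xy <- rbind(xy, H41 = n4 + rot(u, pi / 3) * 1.01,
                  H42 = n4 + rot(u, -pi / 3) * 1.01)
    }
    list(xy = xy, link = "N1", partner = "C2")
  } else stop("no base template for residue code '", code, "'")
}

# ribose + minimal backbone, built once; C1' at the origin.
.sugar_template <- function() {
  ring <- .ring_vertices(c(0, 0), c(1.41, 0), 5, side = -1) # C1' O4' C4' C3' C2'
  xyz <- rbind("C1'" = c(ring[1, ], 0), "O4'" = c(ring[2, ], 0),
               "C4'" = c(ring[3, ], 0), "C3'" = c(ring[4, ], 0),
               "C2'" = c(ring[5, ], 0))
  ctr <- c(colMeans(ring), 0)
  radial <- function(atom, len, dz = 0) {
    u <- xyz[atom, ] - ctr
    u[3] <- 0
    u <- u / sqrt(sum(u^2))
    p <- xyz[atom, ] + u * len
    p[3] <- p[3] + dz
    p
  }
  xyz <- rbind(xyz,
               "O2'" = radial("C2'", 1.41, -0.45),
               "O3'" = radial("C3'", 1.42, -0.45),
               "C5'" = radial("C4'", 1.51, 0.65))
  xyz <- rbind(xyz, "O5'" = xyz["C5'", ] + c(-0.4, 0.6, 1.1))
  xyz <- rbind(xyz, "P" = xyz["O5'", ] + c(0.3, -0.5, 1.4))
  xyz
}

# Build one residue: sugar at `origin`, base attached at torsion chi
# (degrees, reported-range or standard range both accepted).
.build_residue <- function(code, chi, origin = c(0, 0, 0)) {
  sugar <- sweep(.sugar_template(), 2, origin, `+`)
  tpl <- .base_template(code)
  # glycosidic nitrogen off C1', geometry fixed; chi rotates the base
  N <- .place_atom(sugar["C4'", ], sugar["O4'", ], sugar["C1'", ],
                   bond = 1.47, angle = 108, torsion = -120)
  p_link <- tpl$xy[tpl$link, ]
  p_part <- tpl$xy[tpl$partner, ]
  v_part <- p_part - p_link
  blen <- sqrt(sum(v_part^2))
  # angle C1'-N-partner from the template's exocyclic direction
  ring_names <- intersect(rownames(tpl$xy),
                          c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6"))
  nb <- ring_names[vapply(ring_names, function(a)
    a != tpl$link && sqrt(sum((tpl$xy[a, ] - p_link)^2)) < 1.6, logical(1))]
  exo2 <- -(rowSums(vapply(nb, function(a) {
    u <- tpl$xy[a, ] - p_link; u / sqrt(sum(u^2))
  }, numeric(2))) / length(nb))
  exo2 <- exo2 / sqrt(sum(exo2^2))            # template direction of C1'
  cosang <- sum(exo2 * v_part) / blen
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  P3 <- .place_atom(sugar["O4'", ], sugar["C1'", ], N,
                    bond = blen, angle = ang, torsion = chi)
  # in-plane frame: template axes -> 3D axes fixed by (N, C1', partner)
  u3 <- N - sugar["C1'", ]; u3 <- u3 / sqrt(sum(u3^2))  # maps template -exo2
  # 2D template frame anchored on the link: e1 = -exo2 ("away from C1'")
  e1 <- -exo2; e2 <- c(-e1[2], e1[1])
  t_part <- c(sum(v_part * e1), sum(v_part * e2))
  w <- P3 - N - sum((P3 - N) * u3) * u3
  if (abs(t_part[2]) < 1e-8) stop("degenerate base template orientation")
  v3 <- (P3 - N - t_part[1] * u3) / t_part[2]
  base <- t(apply(tpl$xy, 1, function(p) {
    tp <- p - p_link
    t2 <- c(sum(tp * e1), sum(tp * e2))
    N + t2[1] * u3 + t2[2] * v3
  }))
  rbind(sugar, base)
}

# ring center and plane normal of a built base (3D); the normal sign is
# canonicalized against the ring-atom winding so nearby geometries never
# flip orientation
.base_frame <- function(xyz) {
  ring <- intersect(rownames(xyz),
                    c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6"))
  pts <- xyz[ring, , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  normal <- sv$v[, 3]
  wind <- .cross3(pts[1, ] - ctr, pts[2, ] - ctr)
  if (sum(normal * wind) < 0) normal <- -normal
  list(center = ctr, normal = normal)
}
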