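# Seeded generators for every pipeline input: melting-curve datasets with
# known thermodynamics, duplex coordinate frames with prescribed
# conformational states and hydrogen-bond patterns, and energy-component
# tables with known per-state means. Every generator is deterministic given
# its seed and returns its ground truth alongside the data.

#' Ground truth for a synthetic melting dataset
#'
#' @param dH,dS true formation-signed parameters (kcal/mol, eu).
#' @param ct_list total strand concentrations, mol/L; defaults to nine
#'   log-spaced values spanning 1 to 100 micromolar, the usual
#'   dilution-series design.
#' @param baselines `c(m_ss, b_ss, m_ds, b_ds)` baseline coefficients.
#' @param noise_sd absorbance noise, AU (default 0.002).
#' @param temps_C temperature grid, degrees C (default 0-90 in 0.5 steps,
#'   the usual heated-cell ramp).
#' @param duplex_id identifier.
#' @return list of class `melt_truth`.
#' @export
melt_truth <- function(dH, dS, ct_list = 10^seq(-6, -4, length.out = 9),
                       baselines = c(0.0012, 0.95, 2e-4, 0.70),
                       noise_sd = 0.002, temps_C = seq(0, 90, by = 0.5),
                       duplex_id = "synthetic") {
  stopifnot(dH < 0, dS < 0, all(ct_list > 0), noise_sd >= 0)
  structure(list(dH = dH, dS = dS, ct_list = ct_list, baselines = baselines,
                 noise_sd = noise_sd, temps_C = temps_C,
                 duplex_id = duplex_id), class = "melt_truth")
}

#' Generate a synthetic melting-curve dataset
#'
#' One noisy two-state curve per concentration in `truth$ct_list`, plus a
#' manifest table and the truth record, for parameter-recovery testing.
#'
#' @param truth a [melt_truth()].
#' @param seed integer seed (required; identical seeds give identical data).
#' @return list with `curves` (list of [melt_curve()]), `manifest`
#'   (data.frame: `file`, `duplex_id`, `ct_molar`, `run_id`), `truth`.
#' @export
gen_melt_dataset <- function(truth, seed) {
  stopifnot(inherits(truth, "melt_truth"))
  set.seed(seed)
  curves <- lapply(seq_along(truth$ct_list), function(i) {
    simulate_absorbance(truth$dH, truth$dS, truth$ct_list[i],
                        temps_C = truth$temps_C,
                        baselines = truth$baselines,
                        noise_sd = truth$noise_sd,
                        duplex_id = truth$duplex_id,
                        run_id = sprintf("run%d", (i - 1) %/% 3 + 1))
  })
  manifest <- data.frame(
    file = sprintf("%s_curve%02d.tsv", truth$duplex_id,
                   seq_along(curves)),
    duplex_id = truth$duplex_id,
    ct_molar = truth$ct_list,
    run_id = vapply(curves, `[[`, character(1), "run_id"))
  list(curves = curves, manifest = manifest, truth = truth)
}

#' Write a synthetic melting dataset to disk
#'
#' Emits one two-column tab-separated file per curve (`temperature_C`,
#' `absorbance`), a `manifest.tsv` mapping files to duplex and
#' concentration, and a `truth.tsv` sidecar.
#'
#' @param dataset result of [gen_melt_dataset()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_melt_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$curves)) {
    cu <- dataset$curves[[i]]
    utils::write.table(
      data.frame(temperature_C = cu$temps_C, absorbance = cu$absorbance),
      file.path(dir, dataset$manifest$file[i]),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(dataset$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  tr <- dataset$truth
  utils::write.table(
    data.frame(field = c("dH", "dS", "noise_sd", "duplex_id"),
               value = c(tr$dH, tr$dS, tr$noise_sd, tr$duplex_id)),
    file.path(dir, "truth.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Ground truth for synthetic duplex frames
#'
#' Describes the conformational states a synthetic trajectory should
#' populate: per-state middle-pair chi values and a prescribed inter-strand
#' hydrogen-bond count, a state schedule, and the coordinate jitter.
#'
#' @param states named list; names are orientation labels (e.g.
#'   `"anti-anti"`), each element a list with `chi` (length 2: 5'-strand and
#'   3'-strand middle-residue chi, degrees) and `hbonds` (0, 1 or 2).
#' @param schedule either a named probability vector over states or an
#'   explicit character vector of per-frame labels.
#' @param jitter_sd Gaussian coordinate jitter, Angstrom (default 0.05).
#' @param x_code middle residue of the 5' strand (`"A"`, `"7A"`, `"AL"`,
#'   `"7AL"`).
#' @param y_code opposing middle residue (`"A"`, `"C"`, `"G"`, `"U"`).
#' @param n_bp duplex length in base pairs (default 9).
#' @return list of class `conformer_truth`.
#' @export
conformer_truth <- function(states = list(
                              "anti-anti" = list(chi = c(200, 200), hbonds = 2),
                              "syn-anti" = list(chi = c(60, 200), hbonds = 1)),
                            schedule = c("anti-anti" = 0.7, "syn-anti" = 0.3),
                            jitter_sd = 0.05, x_code = "7A", y_code = "A",
                            n_bp = 9) {
  stopifnot(length(states) >= 1, jitter_sd >= 0, n_bp >= 5)
  for (s in states)
    stopifnot(length(s$chi) == 2, s$hbonds %in% 0:2)
  structure(list(states = states, schedule = schedule, jitter_sd = jitter_sd,
                 x_code = x_code, y_code = y_code, n_bp = n_bp),
            class = "conformer_truth")
}

.rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ct * diag(3) + st * rbind(c(0, -u[3], u[2]),
                            c(u[3], 0, -u[1]),
                            c(-u[2], u[1], 0)) +
    (1 - ct) * outer(u, u)
}

# Build one reference frame (all atoms of the duplex) for a given state.
.build_reference_frame <- function(truth, chi_pair, n_hb) {
  n_bp <- truth$n_bp
  mid <- ceiling(n_bp / 2)
  seq_a <- rep("C", n_bp); seq_b <- rep("G", n_bp)
  base9a <- c("U", "C", "A", "G", NA, "C", "A", "G", "U")
  base9b <- c("A", "G", "U", "C", NA, "G", "U", "C", "A")
  if (n_bp == 9) { seq_a <- base9a; seq_b <- base9b }
  seq_a[mid] <- truth$x_code
  seq_b[mid] <- truth$y_code

  rise <- 3.9  # stacked placeholder rise; middle pair drives every analysis
  build_strand <- function(codes, chi_mid) {
    res <- lapply(seq_along(codes), function(i) {
      chi <- if (i == mid) chi_mid else 200
      .build_residue(codes[i], chi, origin = c(0, 0, rise * (i - mid)))
    })
    res
  }
  resA <- build_strand(seq_a, chi_pair[1])
  resB_local <- build_strand(seq_b, chi_pair[2])

  # constructive pairing of the middle bases
  midA <- resA[[mid]]
  midB <- resB_local[[mid]]
  donorsA <- .HB_DONORS[[seq_a[mid]]]
  acceptorsA <- .HB_ACCEPTORS[[seq_a[mid]]]
  donorsB <- .HB_DONORS[[seq_b[mid]]]
  acceptorsB <- .HB_ACCEPTORS[[seq_b[mid]]]
  donA <- donorsA[[1]]
  accA <- acceptorsA[1]
  donB <- donorsB[[1]]
  accB <- acceptorsB[1]
  frA <- .base_frame(midA)
  frB <- .base_frame(midB)
  d_hb <- 2.90
  d_rep <- 3.8   # all non-designed donor-acceptor pairs kept beyond this

  w1 <- midA[donA[2], ] - midA[donA[1], ]
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- midA[accA, ] - frA$center
  w2 <- w2 / sqrt(sum(w2^2))
  acc_t <- midA[donA[1], ] + d_hb * w1          # target for B's acceptor
  don_t <- midA[accA, ] + d_hb * w2             # target for B's donor N
  h_t <- midA[accA, ] + (d_hb - 1.01) * w2      # target for B's donor H

  src <- rbind(midB[accB, ], midB[donB[1], ], midB[donB[2], ],
               midB[accB, ] + frB$normal, midB[donB[1], ] + frB$normal)
  tgt <- rbind(acc_t, don_t, h_t,
               acc_t - frA$normal, don_t - frA$normal)
  kb <- kabsch(tgt, src)
  move <- kb$transform

  # Numerically refine the rigid placement: designed contacts are pulled to
  # ideal geometry (donor-acceptor 2.9 A, near-linear D-H-A) while every
  # other inter-base donor-acceptor pair is pushed beyond the detection
  # distance, so the frame holds exactly the scheduled number of bonds.
  designed <- list()
  if (n_hb >= 1)
    designed[[1]] <- list(side = "A", D = donA[1], H = donA[2], A = accB)
  if (n_hb >= 2)
    designed[[2]] <- list(side = "B", D = donB[1], H = donB[2], A = accA)
  is_designed <- function(side, D, A) {
    for (dd in designed)
      if (dd$side == side && dd$D == D && dd$A == A) return(TRUE)
    FALSE
  }
  othersA <- list()  # donor on A, acceptor on B: (D name, acc name)
  for (dn in donorsA) for (ac in acceptorsB)
    if (!is_designed("A", dn[1], ac))
      othersA[[length(othersA) + 1]] <- c(dn[1], ac)
  othersB <- list()  # donor on B, acceptor on A
  for (dn in donorsB) for (ac in acceptorsA)
    if (!is_designed("B", dn[1], ac))
      othersB[[length(othersB) + 1]] <- c(dn[1], ac)

  b_names <- unique(c(accB, donB[1], donB[2],
                      vapply(othersA, `[`, character(1), 2),
                      vapply(othersB, `[`, character(1), 1)))
  iB <- match(b_names, rownames(midB))
  bi <- function(nm) match(nm, b_names)
  c0 <- colMeans(move(midB))
  ang3 <- function(a, h, d) {
    v1 <- d - h; v2 <- a - h
    acos(pmin(pmax(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) *
      180 / pi
  }
  apply_delta <- function(x, p) {
    R <- .rotation_about_axis(
      if (sum(p[1:3]^2) < 1e-12) c(1, 0, 0) else p[1:3],
      sqrt(sum(p[1:3]^2)) * 180 / pi)
    sweep(sweep(x, 2, c0) %*% t(R), 2, c0 + p[4:6], `+`)
  }
  make_cost <- function(rep_w) function(p) {
    mv <- apply_delta(move(midB[iB, , drop = FALSE]), p)
    cost <- 0
    for (dd in designed) {
      if (dd$side == "A") {
        d1 <- sqrt(sum((midA[dd$D, ] - mv[bi(dd$A), ])^2))
        a1 <- ang3(mv[bi(dd$A), ], midA[dd$H, ], midA[dd$D, ])
      } else {
        d1 <- sqrt(sum((mv[bi(dd$D), ] - midA[dd$A, ])^2))
        a1 <- ang3(midA[dd$A, ], mv[bi(dd$H), ], mv[bi(dd$D), ])
      }
      cost <- cost + (d1 - d_hb)^2 + ((180 - a1) / 60)^2
    }
    if (rep_w > 0) {
      for (o in othersA) {
        d <- sqrt(sum((midA[o[1], ] - mv[bi(o[2]), ])^2))
        if (d < d_rep) cost <- cost + rep_w * (d_rep - d)^2
      }
      for (o in othersB) {
        d <- sqrt(sum((mv[bi(o[1]), ] - midA[o[2], ])^2))
        if (d < d_rep) cost <- cost + rep_w * (d_rep - d)^2
      }
    }
    # quadratic pin: keeps the otherwise-degenerate rotation about the
    # contact axis near its constructive (Kabsch) starting point
    cost + 0.02 * sum(p^2)
  }
  # count realized donor-H-acceptor contacts at the detection cutoffs
  count_contacts <- function(midB_moved) {
    n <- 0
    for (dn in donorsA) for (ac in acceptorsB) {
      d <- sqrt(sum((midA[dn[1], ] - midB_moved[ac, ])^2))
      if (d <= 3.5 &&
          ang3(midB_moved[ac, ], midA[dn[2], ], midA[dn[1], ]) >= 135)
        n <- n + 1
    }
    for (dn in donorsB) for (ac in acceptorsA) {
      d <- sqrt(sum((midB_moved[dn[1], ] - midA[ac, ])^2))
      if (d <= 3.5 &&
          ang3(midA[ac, ], midB_moved[dn[2], ], midB_moved[dn[1], ]) >= 135)
        n <- n + 1
    }
    n
  }
  par_best <- rep(0, 6)
  for (rep_w in c(2, 0.5, 0.1, 0)) {
    cost_fn <- make_cost(rep_w)
    opt <- stats::optim(rep(0, 6), cost_fn,
                        control = list(maxit = 600, reltol = 1e-12))
    opt <- stats::optim(opt$par, cost_fn,
                        control = list(maxit = 600, reltol = 1e-12))
    got <- count_contacts(apply_delta(move(midB), opt$par))
    par_best <- opt$par
    if (got == n_hb || (n_hb == 0 && got >= 0)) break
  }
  base_kabsch <- move
  pref <- par_best
  move <- function(x) apply_delta(base_kabsch(x), pref)

  if (n_hb == 0) {
    base_move <- move
    move <- function(x) sweep(base_move(x), 2, 2.2 * w1, `+`)
  }
  resB <- lapply(resB_local, move)

  atoms <- do.call(rbind, c(
    lapply(seq_along(resA), function(i)
      data.frame(elety = rownames(resA[[i]]), resid = seq_a[i], resno = i,
                 chain = "A")),
    lapply(seq_along(resB), function(i)
      data.frame(elety = rownames(resB[[i]]), resid = seq_b[i], resno = i,
                 chain = "B"))))
  coords <- do.call(rbind, c(resA, resB))
  rownames(coords) <- NULL
  list(coords = coords, atoms = atoms)
}

#' Generate synthetic duplex coordinate frames
#'
#' Builds an idealized `n_bp` duplex with correct residue and atom naming
#' (including the N7-linked adenosine conventions), sets the middle-pair
#' glycosidic torsions and inter-strand hydrogen-bond pattern per the state
#' schedule, adds Gaussian coordinate jitter, and returns the frames with
#' per-frame ground-truth state and bond-count labels.
#'
#' @param truth a [conformer_truth()].
#' @param n_frames number of frames (ignored when `truth$schedule` is an
#'   explicit per-frame label vector).
#' @param seed integer seed.
#' @return list with `frames` (a [frame_set()]), `labels` (per-frame state),
#'   `hbonds` (per-frame prescribed bond count), `reference` (list of
#'   per-state noise-free coordinate matrices), `truth`.
#' @export
gen_duplex_frames <- function(truth, n_frames = 100, seed) {
  stopifnot(inherits(truth, "conformer_truth"))
  set.seed(seed)
  state_names <- names(truth$states)
  labels <- if (is.character(truth$schedule)) truth$schedule
  else sample(state_names, n_frames, replace = TRUE,
              prob = truth$schedule[state_names])
  nf <- length(labels)

  refs <- lapply(state_names, function(s)
    .build_reference_frame(truth, truth$states[[s]]$chi,
                           truth$states[[s]]$hbonds))
  names(refs) <- state_names
  atoms <- refs[[1]]$atoms

  # sanity: prescribed bond counts must hold in the noise-free references
  for (s in state_names) {
    fs1 <- frame_set(refs[[s]]$coords, atoms)
    got <- nrow(detect_hbonds(fs1, 1))
    if (got != truth$states[[s]]$hbonds)
      stop("internal geometry error: state '", s, "' builds ", got,
           " hydrogen bonds instead of ", truth$states[[s]]$hbonds)
  }

  if (length(state_names) > 1) {
    sel_fs <- frame_set(refs[[1]]$coords, atoms)
    sel <- middle_pair_heavy_atoms(sel_fs)
    dmin <- Inf
    for (i in seq_along(state_names)[-1]) for (j in seq_len(i - 1)) {
      dmin <- min(dmin, superpose_rmsd(refs[[i]]$coords[sel, ],
                                       refs[[j]]$coords[sel, ]))
    }
    if (dmin < 4 * truth$jitter_sd)
      warning("reference conformations only ", sprintf("%.2f", dmin),
              " A apart: clustering is ill-posed at jitter ",
              truth$jitter_sd)
  }

  na <- nrow(atoms)
  coords <- array(NA_real_, c(na, 3, nf))
  for (f in seq_len(nf)) {
    base <- refs[[labels[f]]]$coords
    coords[, , f] <- base +
      if (truth$jitter_sd > 0)
        matrix(stats::rnorm(na * 3, 0, truth$jitter_sd), na, 3) else 0
  }
  hb <- vapply(labels, function(s) truth$states[[s]]$hbonds, numeric(1))
  list(frames = frame_set(coords, atoms, provenance = labels),
       labels = labels,
       hbonds = unname(hb),
       reference = lapply(refs, `[[`, "coords"),
       truth = truth)
}

#' Generate a synthetic per-frame energy-component table
#'
#' Per-frame strand and complex components drawn so that the state-wise
#' interaction-energy differences have the prescribed means with Gaussian
#' noise of `noise_sd` on each difference.
#'
#' @param dg_rism named numeric: true per-state mean of
#'   `E_complex - E_s1 - E_s2`, kcal/mol.
#' @param dg_nmode named numeric (same names): true per-state mean of the
#'   normal-mode difference, kcal/mol.
#' @param noise_sd per-difference noise, kcal/mol (default 0.5).
#' @param n_per_state frames per state.
#' @param seed integer seed.
#' @return list with `table` (data.frame in [read_energy_table()] layout)
#'   and `truth` (per-state dG_rism, dG_nmode, dG_pred).
#' @export
gen_energy_table <- function(dg_rism, dg_nmode, noise_sd = 0.5,
                             n_per_state = 1000, seed) {
  stopifnot(length(dg_rism) == length(dg_nmode),
            !is.null(names(dg_rism)),
            all(names(dg_rism) %in% names(dg_nmode)))
  set.seed(seed)
  states <- names(dg_rism)
  tabs <- lapply(states, function(s) {
    n <- n_per_state
    e_s1 <- stats::rnorm(n, -2100, 5)
    e_s2 <- stats::rnorm(n, -2050, 5)
    e_complex <- dg_rism[[s]] + e_s1 + e_s2 + stats::rnorm(n, 0, noise_sd)
    g_s1 <- stats::rnorm(n, -310, 2)
    g_s2 <- stats::rnorm(n, -305, 2)
    g_complex <- dg_nmode[[s]] + g_s1 + g_s2 + stats::rnorm(n, 0, noise_sd)
    data.frame(frame = seq_len(n), state = s,
               e_complex = e_complex, e_s1 = e_s1, e_s2 = e_s2,
               g_nm_complex = g_complex, g_nm_s1 = g_s1, g_nm_s2 = g_s2)
  })
  truth <- data.frame(state = states,
                      dG_rism = as.numeric(dg_rism[states]),
                      dG_nmode = as.numeric(dg_nmode[states]))
  truth$dG_pred <- truth$dG_rism - truth$dG_nmode
  list(table = do.call(rbind, tabs), truth = truth)
}
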