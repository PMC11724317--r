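# Ordered duplex coordinate frames and per-frame conformational analysis:
# glycosidic chi torsions, syn/anti classification, middle-base-pair
# hydrogen bonds, terminal-pair trimming and loop-orientation calls.

# Residue chemistry tables. Codes: A C G U plus the modified residues
# 7A (N7-linked adenosine), AL (LNA-adenosine) and 7AL (N7-LNA-adenosine).
# chi is defined over O4'-C1'-N9-C4 for N9 purines, O4'-C1'-N1-C2 for
# pyrimidines, and O4'-C1'-N7-C5 for the N7-linked residues (base atom
# adjacent to the six-membered ring, by analogy with the N9 definition).
.CHI_ATOMS <- list(
  A   = c("O4'", "C1'", "N9", "C4"),
  G   = c("O4'", "C1'", "N9", "C4"),
  AL  = c("O4'", "C1'", "N9", "C4"),
  C   = c("O4'", "C1'", "N1", "C2"),
  U   = c("O4'", "C1'", "N1", "C2"),
  `7A`  = c("O4'", "C1'", "N7", "C5"),
  `7AL` = c("O4'", "C1'", "N7", "C5"))

# Base-edge donors (donor heavy atom, covalent hydrogen) and acceptors.
# For N7-linked adenines the N9 ring nitrogen is free and becomes an
# acceptor while N7 is the glycosidic nitrogen.
.HB_DONORS <- list(
  A   = list(c("N6", "H61"), c("N6", "H62")),
  `7A`  = list(c("N6", "H61"), c("N6", "H62")),
  AL  = list(c("N6", "H61"), c("N6", "H62")),
  `7AL` = list(c("N6", "H61"), c("N6", "H62")),
  G   = list(c("N1", "H1"), c("N2", "H21"), c("N2", "H22")),
  C   = list(c("N4", "H41"), c("N4", "H42")),
  U   = list(c("N3", "H3")))
.HB_ACCEPTORS <- list(
  A   = c("N1", "N3", "N7"),
  `7A`  = c("N1", "N3", "N9"),
  AL  = c("N1", "N3", "N7"),
  `7AL` = c("N1", "N3", "N9"),
  G   = c("O6", "N3", "N7"),
  C   = c("O2", "N3"),
  U   = c("O2", "O4"))

.KNOWN_RESIDUES <- names(.CHI_ATOMS)

#' Ordered duplex coordinate frames
#'
#' Container for a trajectory-like set of duplex snapshots: a
#' `n_atoms x 3 x n_frames` coordinate array plus an atom table giving atom
#' name, residue code, residue number and strand (chain) for every atom.
#' Atom ordering is identical in every frame.
#'
#' @param coords numeric array, `n_atoms x 3 x n_frames` (a single
#'   `n_atoms x 3` matrix is promoted to one frame).
#' @param atoms data.frame with columns `elety` (atom name), `resid`
#'   (residue code), `resno` (residue number), `chain` (strand id).
#' @param provenance character label(s) recording the source trajectory
#'   (e.g. the started-from orientation), recycled per frame or length 1.
#' @return object of class `frame_set`.
#' @export
frame_set <- function(coords, atoms, provenance = NA_character_) {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[2] == 3)
  need <- c("elety", "resid", "resno", "chain")
  if (!all(need %in% names(atoms)))
    stop("'atoms' must have columns ", paste(need, collapse = ", "))
  if (nrow(atoms) != dim(coords)[1])
    stop("atom table (", nrow(atoms), " rows) does not match coordinates (",
         dim(coords)[1], " atoms)")
  chains <- unique(atoms$chain)
  if (length(chains) != 2)
    stop("a duplex needs exactly 2 chains, found ", length(chains))
  n_res <- vapply(chains, function(ch)
    length(unique(atoms$resno[atoms$chain == ch])), integer(1))
  if (n_res[1] != n_res[2])
    stop("strands differ in length (", n_res[1], " vs ", n_res[2], " residues)")
  nf <- dim(coords)[3]
  if (length(provenance) == 1) provenance <- rep(provenance, nf)
  if (length(provenance) != nf)
    stop("'provenance' must have length 1 or n_frames")
  structure(list(coords = coords, atoms = as.data.frame(atoms),
                 provenance = provenance),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  d <- dim(x$coords)
  ch <- unique(x$atoms$chain)
  cat(sprintf("frame_set: %d frame(s), %d atoms, %d bp duplex (chains %s)\n",
              d[3], d[1],
              length(unique(x$atoms$resno[x$atoms$chain == ch[1]])),
              paste(ch, collapse = "/")))
  invisible(x)
}

#' Number of frames in a frame set
#' @param fs a [frame_set()].
#' @return integer count.
#' @export
n_frames <- function(fs) dim(fs$coords)[3]

#' Middle base pair of a duplex
#'
#' The residue at position `ceiling(n/2)` of each strand, in strand order
#' (5' strand first).
#'
#' @param fs a [frame_set()].
#' @return data.frame with columns `chain`, `resno`, `resid`.
#' @export
middle_pair <- function(fs) {
  chains <- unique(fs$atoms$chain)
  do.call(rbind, lapply(chains, function(ch) {
    resnos <- sort(unique(fs$atoms$resno[fs$atoms$chain == ch]))
    rn <- resnos[ceiling(length(resnos) / 2)]
    data.frame(chain = ch, resno = rn,
               resid = fs$atoms$resid[fs$atoms$chain == ch &
                                        fs$atoms$resno == rn][1])
  }))
}

.atom_index <- function(fs, chain, resno, elety) {
  i <- which(fs$atoms$chain == chain & fs$atoms$resno == resno &
               fs$atoms$elety == elety)
  if (length(i) != 1)
    stop("atom ", elety, " of residue ", resno, " (chain ", chain, ") ",
         if (length(i)) "is ambiguous" else "is missing")
  i
}

.residue_indices <- function(fs, chain, resno, heavy_only = FALSE) {
  i <- which(fs$atoms$chain == chain & fs$atoms$resno == resno)
  if (heavy_only) i <- i[!grepl("^H", fs$atoms$elety[i])]
  i
}

#' Map a chi torsion into the conventional reporting range
#'
#' Wraps angles into `[-90, 270)` so that the syn region is contiguous
#' around 0 and the anti region around 180.
#'
#' @param chi angle(s), degrees.
#' @return angle(s) in `[-90, 270)`.
#' @export
wrap_chi <- function(chi) ((chi + 90) %% 360) - 90

#' Glycosidic chi torsions for one residue across frames
#'
#' chi is O4'-C1'-N9-C4 for N9 purines, O4'-C1'-N1-C2 for pyrimidines, and
#' O4'-C1'-N7-C5 for the N7-linked residues. Angles are mapped into
#' `[-90, 270)` and classified syn/anti by [classify_syn_anti()].
#'
#' @param fs a [frame_set()].
#' @param chain,resno residue selector.
#' @param frames frame indices (default all).
#' @return data.frame with columns `frame`, `chain`, `resno`, `resid`,
#'   `chi`, `state`.
#' @export
chi_for_residue <- function(fs, chain, resno, frames = seq_len(n_frames(fs))) {
  code <- fs$atoms$resid[fs$atoms$chain == chain & fs$atoms$resno == resno][1]
  if (is.na(code)) stop("no residue ", resno, " in chain ", chain)
  if (!code %in% names(.CHI_ATOMS))
    stop("no chi definition for residue code '", code, "'")
  atoms <- .CHI_ATOMS[[code]]
  idx <- vapply(atoms, function(a) .atom_index(fs, chain, resno, a), integer(1))
  chi <- vapply(frames, function(f) {
    xyz <- fs$coords[idx, , f]
    dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
  }, numeric(1))
  chi <- wrap_chi(chi)
  data.frame(frame = frames, chain = chain, resno = resno, resid = code,
             chi = chi, state = classify_syn_anti(chi))
}

#' Classify a glycosidic torsion as syn or anti
#'
#' IUPAC-style +/-90 degree windows around 0 (syn) and 180 (anti) on the
#' `[-90, 270)` scale; the high-anti region folds into anti.
#'
#' @param chi angle(s) in degrees, in `[-90, 270)` (others are wrapped).
#' @return character vector, `"syn"` or `"anti"`.
#' @export
classify_syn_anti <- function(chi) {
  chi <- wrap_chi(chi)
  ifelse(chi >= -90 & chi < 90, "syn", "anti")
}

#' Hydrogen bonds between the middle base pair in one frame
#'
#' Geometric criterion: donor-acceptor heavy-atom distance at most
#' `dist_cutoff` and donor-hydrogen-acceptor angle at least `angle_cutoff`.
#' Only inter-strand base-base donor/acceptor pairs of the two middle
#' residues are considered. Donors and acceptors come from the per-residue
#' chemistry tables; a declared donor with no hydrogen present in the frame
#' is an error.
#'
#' @param fs a [frame_set()].
#' @param frame frame index.
#' @param pair optional data.frame as from [middle_pair()] to analyze a
#'   different residue pair.
#' @param dist_cutoff donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cutoff D-H-A angle cutoff, degrees (default 135).
#' @return data.frame with one row per bond: `donor_chain`, `donor_resno`,
#'   `donor`, `hydrogen`, `acceptor_chain`, `acceptor_resno`, `acceptor`,
#'   `distance`, `angle`.
#' @export
detect_hbonds <- function(fs, frame = 1, pair = middle_pair(fs),
                          dist_cutoff = 3.5, angle_cutoff = 135) {
  stopifnot(nrow(pair) == 2)
  xyz <- fs$coords[, , frame]
  rec <- list()
  for (d in 1:2) {
    a <- 3 - d
    dres <- pair[d, ]; ares <- pair[a, ]
    donors <- .HB_DONORS[[dres$resid]]
    acceptors <- .HB_ACCEPTORS[[ares$resid]]
    if (is.null(donors) || is.null(acceptors))
      stop("no donor/acceptor table for residue code '",
           if (is.null(donors)) dres$resid else ares$resid, "'")
    for (dn in donors) {
      have <- fs$atoms$chain == dres$chain & fs$atoms$resno == dres$resno &
        fs$atoms$elety %in% dn
      if (!any(fs$atoms$elety[have] == dn[1])) next  # donor heavy atom absent
      if (!any(fs$atoms$elety[have] == dn[2]))
        stop("declared donor ", dn[1], " of residue ", dres$resno,
             " (chain ", dres$chain, ") has no hydrogen ", dn[2])
      iD <- .atom_index(fs, dres$chain, dres$resno, dn[1])
      iH <- .atom_index(fs, dres$chain, dres$resno, dn[2])
      for (ac in acceptors) {
        iA <- which(fs$atoms$chain == ares$chain &
                      fs$atoms$resno == ares$resno & fs$atoms$elety == ac)
        if (length(iA) != 1) next
        dDA <- sqrt(sum((xyz[iD, ] - xyz[iA, ])^2))
        if (dDA > dist_cutoff) next
        v1 <- xyz[iD, ] - xyz[iH, ]
        v2 <- xyz[iA, ] - xyz[iH, ]
        ang <- acos(pmin(pmax(sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2))), -1), 1)) * 180 / pi
        if (ang < angle_cutoff) next
        rec[[length(rec) + 1]] <- data.frame(
          donor_chain = dres$chain, donor_resno = dres$resno, donor = dn[1],
          hydrogen = dn[2],
          acceptor_chain = ares$chain, acceptor_resno = ares$resno,
          acceptor = ac, distance = dDA, angle = ang)
      }
    }
  }
  if (!length(rec))
    return(data.frame(donor_chain = character(), donor_resno = integer(),
                      donor = character(), hydrogen = character(),
                      acceptor_chain = character(), acceptor_resno = integer(),
                      acceptor = character(), distance = numeric(),
                      angle = numeric()))
  do.call(rbind, rec)
}

#' Per-frame hydrogen-bond counts of the middle base pair
#'
#' @inheritParams detect_hbonds
#' @param frames frame indices (default all).
#' @return integer vector of per-frame bond counts.
#' @export
hbond_counts <- function(fs, frames = seq_len(n_frames(fs)),
                         pair = middle_pair(fs),
                         dist_cutoff = 3.5, angle_cutoff = 135) {
  vapply(frames, function(f)
    nrow(detect_hbonds(fs, f, pair, dist_cutoff, angle_cutoff)), integer(1))
}

#' Mean hydrogen-bond count over frames
#'
#' Arithmetic mean of per-frame middle-base-pair bond counts -- the
#' "average number of hydrogen bonds" statistic of the comparison tables.
#'
#' @param counts integer vector of per-frame counts, or a [frame_set()]
#'   (counted via [hbond_counts()]).
#' @param ... passed to [hbond_counts()] when `counts` is a frame set.
#' @return dimensionless mean.
#' @export
mean_hbond_count <- function(counts, ...) {
  if (inherits(counts, "frame_set")) counts <- hbond_counts(counts, ...)
  if (!length(counts)) stop("no frames")
  mean(counts)
}

#' Remove terminal base pairs from a duplex frame set
#'
#' Drops `n_pairs` base pairs from each end of the duplex (both strands),
#' the standard preparation before middle-pair energetic and clustering
#' analyses. Residue numbering of the retained core is preserved.
#'
#' @param fs a [frame_set()].
#' @param n_pairs base pairs to remove from each end (default 2).
#' @return a [frame_set()] holding the core.
#' @export
trim_terminal_pairs <- function(fs, n_pairs = 2) {
  chains <- unique(fs$atoms$chain)
  res1 <- sort(unique(fs$atoms$resno[fs$atoms$chain == chains[1]]))
  n <- length(res1)
  if (n <= 2 * n_pairs)
    stop("duplex of ", n, " bp too short to trim ", n_pairs,
         " pairs from each end")
  keep_rows <- rep(FALSE, nrow(fs$atoms))
  for (ch in chains) {
    rs <- sort(unique(fs$atoms$resno[fs$atoms$chain == ch]))
    core <- rs[(n_pairs + 1):(length(rs) - n_pairs)]
    keep_rows <- keep_rows | (fs$atoms$chain == ch & fs$atoms$resno %in% core)
  }
  frame_set(fs$coords[keep_rows, , , drop = FALSE],
            fs$atoms[keep_rows, , drop = FALSE],
            provenance = fs$provenance)
}

#' Joint loop-orientation label of the middle base pair
#'
#' Per frame, the syn/anti states of the two middle residues are joined as
#' `"<5'-strand state>-<3'-strand state>"`. For the whole set the modal
#' label is reported with its fraction; an exact tie is flagged, never
#' broken silently.
#'
#' @param fs a [frame_set()].
#' @param frames frame indices (default all).
#' @return list with `per_frame` (character vector), `label` (modal label,
#'   or tied labels joined with `" | "` when tied), `fraction`, `tie`
#'   (logical), and `table` (label counts).
#' @export
loop_orientation <- function(fs, frames = seq_len(n_frames(fs))) {
  mp <- middle_pair(fs)
  s1 <- chi_for_residue(fs, mp$chain[1], mp$resno[1], frames)$state
  s2 <- chi_for_residue(fs, mp$chain[2], mp$resno[2], frames)$state
  lab <- paste(s1, s2, sep = "-")
  tab <- sort(table(lab), decreasing = TRUE)
  top <- tab[tab == max(tab)]
  tie <- length(top) > 1
  list(per_frame = lab,
       label = paste(names(top), collapse = " | "),
       fraction = unname(max(tab)) / length(lab),
       tie = tie,
       table = tab)
}
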