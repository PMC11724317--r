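# Leader-algorithm clustering of frames on middle-base-pair RMSD and
# cluster-average structures.

#' Atom selection for clustering: middle-pair heavy atoms
#'
#' Indices of the non-hydrogen atoms (sugar + base) of the two middle
#' residues, the default RMSD subset for [leader_cluster()].
#'
#' @param fs a [frame_set()].
#' @return integer atom indices.
#' @export
middle_pair_heavy_atoms <- function(fs) {
  mp <- middle_pair(fs)
  sort(c(.residue_indices(fs, mp$chain[1], mp$resno[1], heavy_only = TRUE),
         .residue_indices(fs, mp$chain[2], mp$resno[2], heavy_only = TRUE)))
}

#' Single-pass leader clustering of frames by superposed RMSD
#'
#' Frames are visited in order; the first frame seeds cluster 1, and each
#' subsequent frame joins the first existing cluster whose *leader* frame is
#' within `threshold` Angstrom superposed RMSD (inclusive), else it seeds a
#' new cluster. Populations are fractions over all frames. The result is
#' order-dependent by construction; combine trajectories in a recorded
#' order before clustering.
#'
#' @param fs a [frame_set()].
#' @param atom_subset atom indices used for the RMSD (default: middle-pair
#'   heavy atoms).
#' @param threshold RMSD threshold, Angstrom (default 0.5).
#' @return object of class `leader_clusters`: `summary` (data.frame with
#'   `cluster`, `leader`, `n`, `population`), `membership` (per-frame
#'   cluster id), `threshold`, `atom_subset`.
#' @export
leader_cluster <- function(fs, atom_subset = middle_pair_heavy_atoms(fs),
                           threshold = 0.5) {
  nf <- n_frames(fs)
  if (nf < 1) stop("no frames to cluster")
  if (length(atom_subset) < 3) stop("atom subset too small for superposition")
  leaders <- integer(0)
  membership <- integer(nf)
  leader_xyz <- list()
  for (f in seq_len(nf)) {
    xyz <- fs$coords[atom_subset, , f]
    placed <- FALSE
    for (k in seq_along(leaders)) {
      if (superpose_rmsd(leader_xyz[[k]], xyz) <= threshold) {
        membership[f] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, f)
      leader_xyz[[length(leaders)]] <- xyz
      membership[f] <- length(leaders)
    }
  }
  n <- tabulate(membership, nbins = length(leaders))
  structure(list(
    summary = data.frame(cluster = seq_along(leaders), leader = leaders,
                         n = n, population = n / nf),
    membership = membership,
    threshold = threshold,
    atom_subset = atom_subset), class = "leader_clusters")
}

#' @export
print.leader_clusters <- function(x, ...) {
  cat(sprintf("Leader clustering: %d cluster(s) at %.2f A over %d frames\n",
              nrow(x$summary), x$threshold, length(x$membership)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Average structure of one cluster
#'
#' Every member frame is superposed onto the cluster leader using the
#' clustering atom subset (the fitted rigid transform is applied to all
#' atoms), then coordinates are averaged per atom.
#'
#' @param clusters a [leader_cluster()] result.
#' @param fs the [frame_set()] that was clustered.
#' @param cluster cluster id.
#' @return `n_atoms x 3` coordinate matrix.
#' @export
average_structure <- function(clusters, fs, cluster = 1) {
  members <- which(clusters$membership == cluster)
  if (!length(members)) stop("cluster ", cluster, " is empty")
  leader <- clusters$summary$leader[clusters$summary$cluster == cluster]
  sel <- clusters$atom_subset
  ref <- fs$coords[sel, , leader]
  acc <- matrix(0, dim(fs$coords)[1], 3)
  for (f in members) {
    fitf <- kabsch(ref, fs$coords[sel, , f])
    acc <- acc + fitf$transform(fs$coords[, , f])
  }
  acc / length(members)
}

#' Per-cluster orientation labels
#'
#' Joins [leader_cluster()] membership with per-frame loop-orientation
#' labels: each cluster is labelled by the modal joint syn/anti state of its
#' member frames (ties flagged in the `tie` column).
#'
#' @param clusters a [leader_cluster()] result.
#' @param fs the clustered [frame_set()].
#' @return the cluster summary data.frame with added `orientation`,
#'   `orientation_fraction` and `tie` columns.
#' @export
cluster_orientations <- function(clusters, fs) {
  lab <- loop_orientation(fs)$per_frame
  out <- clusters$summary
  out$orientation <- NA_character_
  out$orientation_fraction <- NA_real_
  out$tie <- FALSE
  for (k in out$cluster) {
    tab <- sort(table(lab[clusters$membership == k]), decreasing = TRUE)
    top <- tab[tab == max(tab)]
    out$orientation[out$cluster == k] <- paste(names(top), collapse = " | ")
    out$orientation_fraction[out$cluster == k] <- max(tab) / sum(tab)
    out$tie[out$cluster == k] <- length(top) > 1
  }
  out
}
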