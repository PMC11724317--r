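test_that("identical frames collapse to a single full-population cluster", {
  tr <- conformer_truth(states = list(s = list(chi = c(200, 200), hbonds = 2)),
                        schedule = rep("s", 5), jitter_sd = 0)
  g <- gen_duplex_frames(tr, seed = 1)
  cl <- leader_cluster(g$frames)
  expect_equal(nrow(cl$summary), 1)
  expect_equal(cl$summary$population, 1.0)
  expect_equal(cl$membership, rep(1L, 5))
})

test_that("the threshold is inclusive: a frame exactly at the cutoff joins", {
  tr <- conformer_truth(states = list(s = list(chi = c(200, 200), hbonds = 2)),
                        schedule = rep("s", 2), jitter_sd = 0)
  g <- gen_duplex_frames(tr, seed = 1)
  fs <- g$frames
  sel <- middle_pair_heavy_atoms(fs)
  # displace one selected atom so the superposed RMSD is whatever results,
  # then cluster at exactly that threshold
  fs$coords[sel[1], 1, 2] <- fs$coords[sel[1], 1, 2] + 1.5
  d <- superpose_rmsd(fs$coords[sel, , 1], fs$coords[sel, , 2])
  cl_at <- leader_cluster(fs, threshold = d)
  expect_equal(nrow(cl_at$summary), 1)
  cl_below <- leader_cluster(fs, threshold = d * (1 - 1e-6))
  expect_equal(nrow(cl_below$summary), 2)
})

test_that("two-state fixture populations are recovered within 0.02", {
  g <- two_state_frames()
  cl <- leader_cluster(g$frames)
  expect_equal(nrow(cl$summary), 2)
  expect_true(all(cl$summary$population > 0))
  expect_equal(sum(cl$summary$population), 1)
  realized <- as.numeric(table(g$labels)[c("anti-anti", "syn-anti")]) /
    length(g$labels)
  co <- cluster_orientations(cl, g$frames)
  pops <- co$population[match(c("anti-anti", "syn-anti"), co$orientation)]
  expect_lt(max(abs(pops - realized)), 0.02)
  # members satisfy the leader criterion post hoc
  sel <- cl$atom_subset
  for (k in cl$summary$cluster) {
    ref <- g$frames$coords[sel, , cl$summary$leader[k]]
    for (f in which(cl$membership == k))
      expect_lte(superpose_rmsd(ref, g$frames$coords[sel, , f]),
                 cl$threshold + 1e-9)
  }
})

test_that("cluster state labels agree with the generator schedule", {
  g <- two_state_frames()
  cl <- leader_cluster(g$frames)
  co <- cluster_orientations(cl, g$frames)
  lab_by_cluster <- co$orientation[cl$membership]
  expect_gte(mean(lab_by_cluster == g$labels), 0.99)
})

test_that("average_structure is the member mean after superposition", {
  tr <- conformer_truth(states = list(s = list(chi = c(200, 200), hbonds = 2)),
                        schedule = rep("s", 2), jitter_sd = 0)
  g <- gen_duplex_frames(tr, seed = 1)
  fs <- g$frames
  cl <- leader_cluster(fs)
  # single-member cluster: average is the frame itself
  one <- frame_set(fs$coords[, , 1, drop = FALSE], fs$atoms)
  cl1 <- leader_cluster(one)
  expect_equal(average_structure(cl1, one, 1), fs$coords[, , 1],
               tolerance = 1e-12, ignore_attr = TRUE)
  # +d / -d perturbation outside the fitted subset averages to the midpoint
  sel <- middle_pair_heavy_atoms(fs)
  out <- setdiff(seq_len(nrow(fs$atoms)), sel)[1]
  fs$coords[out, , 1] <- fs$coords[out, , 1] + c(0.3, 0, 0)
  fs$coords[out, , 2] <- fs$coords[out, , 2] - c(0.3, 0, 0)
  cl2 <- leader_cluster(fs)
  avg <- average_structure(cl2, fs, 1)
  expect_equal(avg[out, ], g$frames$coords[out, , 1], tolerance = 1e-9)
  expect_error(average_structure(cl2, fs, 99), "empty")
})

test_that("jittered cluster averages converge on the reference geometry", {
  tr <- conformer_truth(states = list(s = list(chi = c(200, 200), hbonds = 2)),
                        schedule = c(s = 1), jitter_sd = 0.05)
  g <- gen_duplex_frames(tr, n_frames = 200, seed = 31)
  cl <- leader_cluster(g$frames)
  expect_equal(nrow(cl$summary), 1)
  avg <- average_structure(cl, g$frames, 1)
  ref <- g$reference$s
  # compare in a common frame
  sel <- middle_pair_heavy_atoms(g$frames)
  fit <- kabsch(ref[sel, ], avg[sel, ])
  d <- sqrt(rowSums((fit$transform(avg)[sel, ] - ref[sel, ])^2))
  expect_lt(mean(d), 0.01)
  expect_lt(max(d), 0.03)
})
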