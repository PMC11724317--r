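test_that("generator chi values round-trip exactly at zero jitter", {
  tr <- conformer_truth(states = list(
    "anti-anti" = list(chi = c(200, 200), hbonds = 2),
    "syn-anti" = list(chi = c(60, 200), hbonds = 1)),
    schedule = c("syn-anti", "anti-anti"), jitter_sd = 0)
  g <- gen_duplex_frames(tr, seed = 1)
  fs <- g$frames
  mp <- middle_pair(fs)
  expect_equal(mp$resid, c("7A", "A"))
  c1 <- chi_for_residue(fs, mp$chain[1], mp$resno[1])
  c2 <- chi_for_residue(fs, mp$chain[2], mp$resno[2])
  expect_equal(c1$chi, c(60, 200), tolerance = 1e-8)
  expect_equal(c2$chi, c(200, 200), tolerance = 1e-8)
  expect_equal(c1$state, c("syn", "anti"))
})

test_that("chi stays near truth under 0.05 A coordinate jitter", {
  tr <- conformer_truth(states = list(s = list(chi = c(60, 200), hbonds = 2)),
                        schedule = rep("s", 50), jitter_sd = 0.05)
  g <- gen_duplex_frames(tr, seed = 5)
  mp <- middle_pair(g$frames)
  chi <- chi_for_residue(g$frames, mp$chain[1], mp$resno[1])$chi
  # 0.05 A on the four torsion atoms propagates to a ~7 degree spread
  expect_lt(abs(mean(chi) - 60), 3)
  expect_lt(sd(chi), 10)
  # states never flip at this jitter (syn/anti boundaries are 90 deg away)
  expect_true(all(classify_syn_anti(chi) == "syn"))
})

test_that("chi is defined per linkage chemistry and errors on missing atoms", {
  tr <- conformer_truth(x_code = "A", y_code = "U", states = list(
    s = list(chi = c(200, 200), hbonds = 2)), schedule = "s", jitter_sd = 0)
  g <- gen_duplex_frames(tr, seed = 1)
  # pyrimidine chi (O4'-C1'-N1-C2) equally exact
  mp <- middle_pair(g$frames)
  expect_equal(chi_for_residue(g$frames, "B", mp$resno[2])$chi, 200,
               tolerance = 1e-8)
  expect_error(chi_for_residue(g$frames, "A", 99), "no residue")
})

test_that("syn/anti classification follows the +/-90 degree windows", {
  expect_equal(classify_syn_anti(60), "syn")
  expect_equal(classify_syn_anti(200), "anti")
  expect_equal(classify_syn_anti(265), "anti")   # high-anti folds into anti
  expect_equal(classify_syn_anti(-89.9), "syn")
  expect_equal(classify_syn_anti(c(89.9, 90)), c("syn", "anti"))
  expect_equal(classify_syn_anti(270), "syn")    # wraps to -90
})

test_that("hydrogen-bond detection applies both geometric cutoffs", {
  tr <- conformer_truth(jitter_sd = 0)
  g <- gen_duplex_frames(tr, seed = 1)
  fs <- g$frames
  i <- which(g$labels == "anti-anti")[1]
  hb <- detect_hbonds(fs, i)
  expect_equal(nrow(hb), 2)
  expect_true(all(hb$distance <= 3.5))
  expect_true(all(hb$angle >= 135))
  # tightening the distance cutoff below the built bond length removes bonds
  expect_equal(nrow(detect_hbonds(fs, i, dist_cutoff = 2.0)), 0)
  # bending one donor hydrogen below the angle cutoff removes that bond only
  fs2 <- fs
  iH <- which(fs2$atoms$chain == "A" & fs2$atoms$resno == 5 &
                fs2$atoms$elety == "H61")
  iD <- which(fs2$atoms$chain == "A" & fs2$atoms$resno == 5 &
                fs2$atoms$elety == "N6")
  hb1 <- hb[hb$donor_chain == "A", ]
  iA <- which(fs2$atoms$chain == "B" & fs2$atoms$resno == 5 &
                fs2$atoms$elety == hb1$acceptor)
  v <- fs2$coords[iA, , i] - fs2$coords[iD, , i]
  perp <- .cross3_test(v, c(0, 0, 1))
  fs2$coords[iH, , i] <- fs2$coords[iD, , i] + perp / sqrt(sum(perp^2))
  hb2 <- detect_hbonds(fs2, i)
  expect_equal(nrow(hb2), 1)
  expect_equal(hb2$donor_chain, "B")
})

test_that("mean hydrogen-bond count is an order-invariant arithmetic mean", {
  expect_equal(mean_hbond_count(c(2, 2, 1, 2)), 1.75)
  expect_equal(mean_hbond_count(c(2, 2, 2)), 2)
  expect_equal(mean_hbond_count(c(2, 1, 2, 2)), mean_hbond_count(c(1, 2, 2, 2)))
  expect_error(mean_hbond_count(integer(0)), "no frames")
})

test_that("scheduled bond patterns are reproduced under jitter", {
  g <- two_state_frames()
  counts <- hbond_counts(g$frames)
  expect_equal(counts, g$hbonds)
  sched_mean <- mean(g$hbonds)
  expect_lt(abs(mean_hbond_count(counts) - sched_mean), 0.05)
})

test_that("terminal-pair trimming keeps the core and validates length", {
  tr <- conformer_truth(jitter_sd = 0)
  g <- gen_duplex_frames(tr, n_frames = 2, seed = 1)
  core <- trim_terminal_pairs(g$frames)
  per_chain <- table(unique(core$atoms[c("chain", "resno")])$chain)
  expect_equal(as.integer(per_chain), c(5L, 5L))
  expect_equal(sort(unique(core$atoms$resno)), 3:7)
  core1 <- trim_terminal_pairs(core, 2)
  expect_equal(length(unique(core1$atoms$resno)), 1)
  expect_error(trim_terminal_pairs(core1), "too short")
  # middle pair unchanged by trimming
  expect_equal(middle_pair(core)$resid, middle_pair(g$frames)$resid)
})

test_that("loop orientation reports modal label and flags ties", {
  g <- two_state_frames()
  lo <- loop_orientation(g$frames)
  expect_equal(lo$per_frame, g$labels)
  expect_equal(lo$label, "anti-anti")
  expect_false(lo$tie)
  expect_gt(lo$fraction, 0.6)
  # explicit 50/50 mixture is a flagged tie
  tr <- conformer_truth(states = list(
    "anti-anti" = list(chi = c(200, 200), hbonds = 2),
    "syn-anti" = list(chi = c(60, 200), hbonds = 1)),
    schedule = rep(c("anti-anti", "syn-anti"), 5), jitter_sd = 0)
  g2 <- gen_duplex_frames(tr, seed = 2)
  lo2 <- loop_orientation(g2$frames)
  expect_true(lo2$tie)
  expect_match(lo2$label, "\\|")
})

test_that("frame_set validates its structural invariants", {
  tr <- conformer_truth(jitter_sd = 0)
  g <- gen_duplex_frames(tr, n_frames = 1, seed = 1)
  expect_error(frame_set(g$frames$coords[1:10, , , drop = FALSE],
                         g$frames$atoms), "does not match")
  at <- g$frames$atoms
  at$chain <- "A"
  expect_error(frame_set(g$frames$coords, at), "2 chains")
})
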