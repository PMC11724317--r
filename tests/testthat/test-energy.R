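test_that("aggregate_state computes the two-term decomposition", {
  fr <- data.frame(frame = 1, state = "anti-anti",
                   e_complex = -100, e_s1 = -60, e_s2 = -35,
                   g_nm_complex = -20, g_nm_s1 = -12, g_nm_s2 = -9)
  ag <- aggregate_state(fr)
  expect_equal(ag$dG_rism, -5)
  expect_equal(ag$dG_nmode, 1)
  expect_equal(ag$dG_pred, -6)
  z <- fr; z[, 3:8] <- 0
  expect_equal(aggregate_state(z)$dG_pred, 0)
  expect_error(aggregate_state(fr, states = "missing"), "no frames")
  expect_error(aggregate_state(fr[, -3]), "lacks column")
})

test_that("aggregation is frame-order invariant and linear", {
  et <- gen_energy_table(c(a = 1.0, b = -2.0), c(a = 0.5, b = 0.1),
                         noise_sd = 0.3, n_per_state = 50, seed = 8)
  tab <- et$table
  a1 <- aggregate_state(tab)
  a2 <- aggregate_state(tab[sample(nrow(tab)), ])
  expect_equal(a1$dG_pred, a2$dG_pred[match(a1$state, a2$state)])
  # linearity: scaling every component scales the aggregate
  tab2 <- tab
  tab2[, 3:8] <- 2 * tab2[, 3:8]
  expect_equal(aggregate_state(tab2)$dG_pred, 2 * a1$dG_pred)
})

test_that("synthetic energy tables recover their per-state truth", {
  et <- gen_energy_table(c("anti-anti" = 1.5, "syn-anti" = 2.1),
                         c("anti-anti" = 0, "syn-anti" = 0),
                         noise_sd = 0.5, n_per_state = 1000, seed = 3)
  ag <- aggregate_state(et$table)
  expect_equal(ag$dG_pred, et$truth$dG_pred, tolerance = 0.05)
  gm <- global_minimum(ag)
  expect_equal(gm$minimum$state, "anti-anti")
  # noise-free: exact recovery
  et0 <- gen_energy_table(c(x = -1.2), c(x = 0.4), noise_sd = 0,
                          n_per_state = 10, seed = 1)
  expect_equal(aggregate_state(et0$table)$dG_pred, -1.6, tolerance = 1e-12)
})

test_that("ddg_pred reproduces published predicted differences", {
  expect_equal(ddg_pred(5.43, 1.86), 3.57)
  expect_equal(ddg_pred(1.50, 3.48), -1.98)
  expect_equal(ddg_pred(2, 2), 0)
})

test_that("global_minimum applies the 2.5 kcal/mol alternate window", {
  st <- aggregate_state(data.frame(
    frame = 1:2, state = c("anti-anti", "syn-anti"),
    e_complex = c(1.50, 2.60), e_s1 = 0, e_s2 = 0,
    g_nm_complex = 0, g_nm_s1 = 0, g_nm_s2 = 0))
  gm <- global_minimum(st)
  expect_equal(gm$minimum$state, "anti-anti")
  expect_equal(gm$alternates$state, "syn-anti")  # 1.10 <= 2.5: co-populated
  gm2 <- global_minimum(st, tie_window = 1.0)
  expect_equal(nrow(gm2$alternates), 0)
  one <- global_minimum(st[1, ])
  expect_equal(one$minimum$state, "anti-anti")
})

test_that("the packaged energetics table names the published minima", {
  tab <- duplex_energy_table()
  r <- tab[tab$duplex_id == "7AL-G", ]
  expect_equal(r$orientation_pred, "syn-anti")
  expect_equal(r$dg_pred, 1.22)
})

test_that("overstabilization is the experiment-minus-prediction gap", {
  expect_equal(overstabilization(0.99, -0.71), 1.70)
  expect_equal(overstabilization(4.15, 3.57), 0.58)
  expect_equal(overstabilization(1.1, 1.1), 0)
})

test_that("energy tables round-trip through the reader with validation", {
  et <- gen_energy_table(c(a = 1), c(a = 0), noise_sd = 0.1,
                         n_per_state = 5, seed = 2)
  f <- tempfile(fileext = ".tsv")
  write.table(et$table, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_energy_table(f)
  expect_equal(back$e_complex, et$table$e_complex)
  bad <- et$table
  bad$e_s1[2] <- NA
  write.table(bad, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_energy_table(f), "e_s1")
  write.table(et$table[, -4], f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_energy_table(f), "lacks column")
})
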