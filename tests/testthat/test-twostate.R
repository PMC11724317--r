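test_that("fraction_duplex solves the two-state mass balance", {
  # K*ct = 4 is the melting-temperature condition, f = 1/2
  expect_equal(fraction_duplex(4 / 1e-4, 1e-4), 0.5)
  expect_equal(fraction_duplex(0, 1e-4), 0)
  # K*ct = 8: closed form (9 - sqrt(17))/8, cross-checked against a numeric
  # root of K = 2f/((1-f)^2 ct)
  f <- fraction_duplex(8 / 1e-5, 1e-5)
  expect_equal(f, (9 - sqrt(17)) / 8)
  root <- uniroot(function(x) 8 / 1e-5 - 2 * x / ((1 - x)^2 * 1e-5),
                  c(1e-12, 1 - 1e-9), tol = 1e-14)$root
  expect_equal(f, root, tolerance = 1e-9)
  # mass-balance residual across a grid
  for (a in c(1e-6, 0.1, 1, 42, 1e5)) {
    f <- fraction_duplex(a / 2e-5, 2e-5)
    expect_equal(2 * f / ((1 - f)^2 * 2e-5), a / 2e-5, tolerance = 1e-8)
  }
  expect_error(fraction_duplex(NA, 1e-4), "finite")
  expect_error(fraction_duplex(1, -1), "ct")
})

test_that("fraction_duplex decreases in temperature and is 1/2 at Tm", {
  dH <- -68.4; dS <- -195.4; ct <- 1e-4
  tms <- seq(0, 90, by = 1) + 273.15
  f <- fraction_duplex(k_twostate(dH, dS, tms), ct)
  expect_true(all(diff(f) < 0))
  tm_K <- tm_at_concentration(dH, dS, ct) + 273.15
  expect_equal(fraction_duplex(k_twostate(dH, dS, tm_K), ct), 0.5,
               tolerance = 1e-12)
})

test_that("dg_at_temperature reproduces published free energies", {
  expect_equal(dg_at_temperature(-67.6, -187.0), -9.60, tolerance = 0.005)
  expect_equal(dg_at_temperature(-68.4, -195.4), -7.80, tolerance = 0.005)
  expect_equal(dg_at_temperature(0, 0, 300), 0)
})

test_that("tm_at_concentration matches published melting temperatures", {
  expect_equal(tm_at_concentration(-67.6, -187.0, 1e-4), 51.8, tolerance = 0.1)
  expect_equal(tm_at_concentration(-68.4, -195.4, 1e-4), 42.8, tolerance = 0.1)
  # ln(ct/4) vanishes at ct = 4 M: Tm = 1000 dH/dS
  expect_equal(tm_at_concentration(-70, -200, 4), 350 - 273.15)
  expect_error(tm_at_concentration(-70, 200, 1e-4), "sign")
})

test_that("tm_at_concentration is strictly increasing in concentration", {
  cts <- 10^seq(-6, -3, length.out = 12)
  tms <- vapply(cts, function(ct) tm_at_concentration(-70, -200, ct), numeric(1))
  expect_true(all(diff(tms) > 0))
})

test_that("absorbance model hits the baseline midpoint at Tm", {
  dH <- -70; dS <- -200; ct <- 1e-4
  tm <- tm_at_concentration(dH, dS, ct)
  A <- absorbance_twostate(dH, dS, ct, c(tm - 30, tm, tm + 30),
                           baselines = c(0, 1.0, 0, 0.6))
  expect_equal(A[2], 0.8, tolerance = 1e-10)  # f = 1/2, flat baselines
  # high-temperature limit approaches the single-strand baseline
  A90 <- absorbance_twostate(dH, dS, ct, 90, baselines = c(0, 1.0, 0, 0.6))
  expect_lt(abs(A90 - 1.0), 1e-3)
  expect_error(absorbance_twostate(0, -200, ct, 50), "transition")
})

test_that("melt_curve validates its invariants", {
  expect_error(melt_curve(1:10, rnorm(10), 1e-5), "20 points")
  expect_error(melt_curve(c(1:19, 19), rnorm(20), 1e-5), "increasing")
  expect_error(melt_curve(1:20, rnorm(20), 0), "ct")
  expect_error(melt_curve(1:20, rnorm(19), 1e-5), "equal length")
  cu <- melt_curve(1:20, rnorm(20), 1e-5, duplex_id = "x")
  expect_s3_class(cu, "melt_curve")
  expect_output(print(cu), "20 points")
})

test_that("nearest-neighbour extinction follows the dimer-monomer formula", {
  tab <- extinction_table()
  expect_equal(extinction_nn("A"), unname(tab$monomer["A"]))
  expect_equal(extinction_nn("AA"), unname(2 * tab$dimer["AA"]))
  # n = 3: 2*(eps_AA + eps_AA) - eps_A, the published nearest-neighbour rule
  expect_equal(extinction_nn("AAA"),
               unname(4 * tab$dimer["AA"] - tab$monomer["A"]))
  # independent recomputation for a mixed sequence
  s <- c("U", "C", "A", "G", "A", "C", "A", "G", "U")
  manual <- 2 * sum(tab$dimer[paste0(s[-9], s[-1])]) - sum(tab$monomer[s[2:8]])
  expect_equal(extinction_nn(s), unname(manual))
  expect_error(extinction_nn("AXA"), "unknown residue")
  # modified residues alias to A with a warning
  expect_warning(e7 <- extinction_nn(c("U", "7A", "U")), "7A")
  expect_equal(e7, suppressWarnings(extinction_nn(c("U", "A", "U"))),
               ignore_attr = TRUE)
  expect_equal(suppressWarnings(extinction_nn(c("U", "7A", "U"))),
               extinction_nn(c("U", "A", "U")))
})

test_that("strand concentration follows Beer-Lambert", {
  expect_equal(strand_concentration(0.5, 1e5, 1), 5e-6)
  expect_equal(strand_concentration(1.0, 2e5, 1), 5e-6)
  expect_error(strand_concentration(0, 1e5, 1), "> 0")
  expect_error(strand_concentration(0.5, -1, 1), "> 0")
})
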