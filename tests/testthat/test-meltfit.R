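test_that("noise-free curves round-trip through the six-parameter fit", {
  # grid over the physically relevant parameter box, keeping combinations
  # whose transition actually falls inside the 0-90 degC measuring window
  n_tested <- 0
  for (dH in c(-90, -75, -50)) for (dS in c(-250, -204.1, -150)) {
    for (ct in c(1e-6, 5e-5, 1e-4)) {
      tm <- tryCatch(tm_at_concentration(dH, dS, ct),
                     error = function(e) NA_real_)
      # both baselines must be visible inside the window for the six
      # parameters to be identifiable
      if (!is.finite(tm) || tm < 25 || tm > 70) next
      cu <- simulate_absorbance(dH, dS, ct)
      f <- fit_melt_curve(cu)
      expect_true(f$converged)
      expect_lt(abs(f$dH - dH) / abs(dH), 1e-3)
      expect_lt(abs(f$dS - dS) / abs(dS), 1e-3)
      n_tested <- n_tested + 1
    }
  }
  expect_gte(n_tested, 6)
})

test_that("fit recovers parameters from noisy curves at fixed seed", {
  set.seed(42)
  cu <- simulate_absorbance(-75, -204.1, 5e-5, noise_sd = 0.002)
  f <- fit_melt_curve(cu)
  expect_true(f$converged)
  expect_lt(abs(f$dH + 75) / 75, 0.05)
  expect_equal(f$dG37, dg_at_temperature(f$dH, f$dS))
  expect_lt(f$rms_residual, 0.004)
})

test_that("featureless input is reported as non-converged, never garbage", {
  lin <- melt_curve(seq(0, 90, 0.5), 0.8 + 0.001 * seq(0, 90, 0.5), 1e-5)
  f <- fit_melt_curve(lin)
  expect_false(f$converged)
  expect_match(f$message, "transition|converge|amplitude")
  expect_error(residuals(f), "converge")
  expect_error(predict(f), "converge")
})

test_that("fitting window truncation changes the data actually fitted", {
  cu <- simulate_absorbance(-70, -195, 1e-4)
  f_full <- fit_melt_curve(cu)
  f_win <- fit_melt_curve(cu, window = c(10, 80))
  expect_true(f_win$converged)
  expect_lt(abs(f_win$dH - f_full$dH), 0.5)
  expect_error(fit_melt_curve(cu, window = c(44, 46)), "20 points")
})

test_that("melt_fit methods are coherent", {
  cu <- simulate_absorbance(-70, -195, 1e-4)
  f <- fit_melt_curve(cu)
  expect_named(coef(f), c("dH", "dS", "dG37", "tm_C",
                          "m_ss", "b_ss", "m_ds", "b_ds"))
  expect_equal(max(abs(residuals(f))), 0, tolerance = 1e-8)
  expect_equal(predict(f, 50),
               absorbance_twostate(f$dH, f$dS, 1e-4, 50,
                                   c(coef(f)[c("m_ss", "b_ss", "m_ds", "b_ds")])),
               ignore_attr = TRUE)
  sims <- simulate(f, nsim = 2, seed = 1, noise_sd = 0.002)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "melt_curve")
  expect_false(identical(sims[[1]]$absorbance, sims[[2]]$absorbance))
  expect_output(print(f), "kcal/mol")
})

test_that("average_curve_fits averages per-curve dG37, not recomputed values", {
  mk <- function(dH, dS) {
    cu <- simulate_absorbance(dH, dS, 1e-4)
    fit_melt_curve(cu)
  }
  fits <- list(mk(-70, -196), mk(-72, -202), mk(-74, -208))
  avg <- average_curve_fits(fits)
  expect_equal(avg$dH, -72, tolerance = 1e-3)
  expect_equal(avg$sd_dH, 2, tolerance = 1e-2)
  # dG37 must equal the mean of per-curve values
  expect_equal(avg$dG37, mean(vapply(fits, `[[`, numeric(1), "dG37")))
  # ... which differs from recomputation off the averaged dH/dS in general
  expect_equal(avg$source, "curve_fit_average")
  expect_error(average_curve_fits(fits[1]), "at least 2")
})

test_that("identical fits average with zero spread", {
  cu <- simulate_absorbance(-70, -196, 1e-4)
  f <- fit_melt_curve(cu)
  avg <- average_curve_fits(list(f, f, f))
  expect_equal(avg$sd_dH, 0)
  expect_equal(avg$sd_dG37, 0)
})

test_that("nine noisy synthetic curves recover the generating enthalpy", {
  tr <- melt_truth(-68.4, -195.4)
  ds <- gen_melt_dataset(tr, seed = 11)
  fits <- lapply(ds$curves, fit_melt_curve)
  avg <- average_curve_fits(fits)
  expect_lt(abs(avg$dH - tr$dH), max(3 * avg$sd_dH, 1))
})
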