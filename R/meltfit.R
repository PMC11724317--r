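# Per-curve two-state fits (6 parameters: dH, dS and two linear baselines),
# averaging of curve fits, and the classed S3 model object.

.baseline_guess <- function(temps, abs_, frac = 0.15) {
  n <- length(temps)
  k <- max(3L, ceiling(frac * n))
  lo <- seq_len(k)                # low T: duplex baseline
  hi <- seq.int(n - k + 1L, n)    # high T: single-strand baseline
  ds <- stats::coef(stats::lm(abs_[lo] ~ temps[lo]))
  ss <- stats::coef(stats::lm(abs_[hi] ~ temps[hi]))
  c(m_ss = unname(ss[2]), b_ss = unname(ss[1]),
    m_ds = unname(ds[2]), b_ds = unname(ds[1]))
}

.tm_guess <- function(temps, abs_) {
  # max of smoothed dA/dT locates the inflection
  k <- max(3L, min(9L, length(abs_) %/% 10))
  sm <- stats::filter(abs_, rep(1 / k, k), sides = 2)
  dA <- diff(as.numeric(sm)) / diff(temps)
  mid <- temps[-length(temps)] + diff(temps) / 2
  ok <- is.finite(dA)
  if (!any(ok)) return(stats::median(temps))
  mid[ok][which.max(dA[ok])]
}

#' Fit a single melting curve to the two-state model
#'
#' Least-squares fit of the six-parameter model (formation enthalpy and
#' entropy plus independent linear single- and double-strand baselines) to
#' one absorbance-versus-temperature curve, by Levenberg-Marquardt
#' minimization. The melting temperature is computed from the fitted
#' `dH`/`dS` at the curve's own strand concentration.
#'
#' Default initialization: baselines from linear fits to the first/last 15%
#' of points, `dH = -70` kcal/mol, and the Tm guess at the maximum of the
#' smoothed dA/dT. Non-convergence (or convergence to a physically
#' meaningless transition) is reported through `converged = FALSE` with a
#' diagnostic message, never as silent garbage.
#'
#' @param curve a [melt_curve()].
#' @param init optional named list overriding initial guesses
#'   (`dH`, `dS`, `tm_C`, `baselines`).
#' @param window optional `c(Tmin, Tmax)` in degrees C: points outside are
#'   dropped before fitting (curve-truncation flexibility).
#' @param max_iter,ftol Levenberg-Marquardt iteration cap and relative
#'   cost-change tolerance.
#' @return object of class `melt_fit` with components `dH`, `dS` (kcal/mol,
#'   eu, formation-signed), `dG37`, `tm_C`, `baseline_ss`, `baseline_ds`,
#'   `rms_residual`, `converged`, `message`, `curve`, `fitted`.
#' @seealso [average_curve_fits()], [vant_hoff()]
#' @export
fit_melt_curve <- function(curve, init = NULL, window = NULL,
                           max_iter = 500, ftol = 1e-10) {
  stopifnot(inherits(curve, "melt_curve"))
  temps <- curve$temps_C
  abs_ <- curve$absorbance
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    keep <- temps >= window[1] & temps <= window[2]
    if (sum(keep) < 20)
      stop("fewer than 20 points remain inside the fitting window")
    temps <- temps[keep]
    abs_ <- abs_[keep]
  }
  ct <- curve$ct

  bl <- .baseline_guess(temps, abs_)
  tm0 <- .tm_guess(temps, abs_)
  dH0 <- -70
  dS0 <- 1000 * dH0 / (tm0 + .KELVIN) - .RGAS * log(ct / 4)
  if (!is.null(init)) {
    if (!is.null(init$dH)) dH0 <- init$dH
    if (!is.null(init$tm_C)) tm0 <- init$tm_C
    if (!is.null(init$baselines)) bl[] <- init$baselines
    dS0 <- if (!is.null(init$dS)) init$dS else
      1000 * dH0 / (tm0 + .KELVIN) - .RGAS * log(ct / 4)
  }

  dat <- data.frame(T_C = temps, A = abs_)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      A ~ absorbance_twostate(dH, dS, ct, T_C, c(m_ss, b_ss, m_ds, b_ds)),
      data = dat,
      start = list(dH = unname(dH0), dS = unname(dS0),
                   m_ss = unname(bl["m_ss"]), b_ss = unname(bl["b_ss"]),
                   m_ds = unname(bl["m_ds"]), b_ds = unname(bl["b_ds"])),
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol)),
    error = function(e) e)

  out <- structure(list(
    dH = NA_real_, dS = NA_real_, dG37 = NA_real_, tm_C = NA_real_,
    baseline_ss = c(slope = NA_real_, intercept = NA_real_),
    baseline_ds = c(slope = NA_real_, intercept = NA_real_),
    rms_residual = NA_real_, converged = FALSE, message = "",
    curve = curve, window = window, fitted = NULL), class = "melt_fit")

  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(out)
  }
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  dH <- unname(cf["dH"]); dS <- unname(cf["dS"])
  out$dH <- dH; out$dS <- dS
  out$baseline_ss <- c(slope = unname(cf["m_ss"]), intercept = unname(cf["b_ss"]))
  out$baseline_ds <- c(slope = unname(cf["m_ds"]), intercept = unname(cf["b_ds"]))
  out$rms_residual <- sqrt(mean(res^2))
  out$fitted <- stats::fitted(fit)

  if (!all(is.finite(cf))) {
    out$message <- "non-finite parameter estimates"
    return(out)
  }
  if (dH >= -1 || dS >= 0) {
    out$message <- "no resolvable two-state transition (dH/dS not negative)"
    return(out)
  }
  tm <- tryCatch(tm_at_concentration(dH, dS, ct), error = function(e) NA_real_)
  if (!is.finite(tm)) {
    out$message <- "fitted parameters give no physical melting temperature"
    return(out)
  }
  # degenerate (featureless) input: baseline separation at the transition is
  # negligible against the absorbance span
  amp <- abs((cf["m_ss"] * tm + cf["b_ss"]) - (cf["m_ds"] * tm + cf["b_ds"]))
  if (amp < 0.05 * diff(range(abs_))) {
    out$message <- "no resolvable two-state transition (negligible amplitude)"
    return(out)
  }
  out$tm_C <- tm
  out$dG37 <- dg_at_temperature(dH, dS)
  out$converged <- TRUE
  if (tm < min(temps) || tm > max(temps))
    warning("fitted Tm (", sprintf("%.1f", tm),
            " degC) lies outside the measured temperature span")
  out
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Two-state melt fit '%s' (ct = %.3g M)\n",
              x$curve$duplex_id, x$curve$ct))
  if (x$converged) {
    cat(sprintf("  dH = %.1f kcal/mol, dS = %.1f eu, dG37 = %.2f kcal/mol, Tm = %.1f degC\n",
                x$dH, x$dS, x$dG37, x$tm_C))
    cat(sprintf("  rms residual %.2g AU\n", x$rms_residual))
  } else {
    cat("  did not converge:", x$message, "\n")
  }
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(dH = object$dH, dS = object$dS, dG37 = object$dG37, tm_C = object$tm_C,
    m_ss = unname(object$baseline_ss["slope"]),
    b_ss = unname(object$baseline_ss["intercept"]),
    m_ds = unname(object$baseline_ds["slope"]),
    b_ds = unname(object$baseline_ds["intercept"]))
}

#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  temps <- if (is.null(newdata)) object$curve$temps_C else
    if (is.list(newdata)) newdata$temps_C else as.numeric(newdata)
  absorbance_twostate(object$dH, object$dS, object$curve$ct, temps,
                      c(object$baseline_ss["slope"], object$baseline_ss["intercept"],
                        object$baseline_ds["slope"], object$baseline_ds["intercept"]))
}

#' @export
residuals.melt_fit <- function(object, ...) {
  if (!object$converged) stop("no residuals: fit did not converge")
  object$curve$absorbance - predict(object)
}

#' @export
fitted.melt_fit <- function(object, ...) predict(object)

#' @export
summary.melt_fit <- function(object, ...) {
  object
}

#' @export
plot.melt_fit <- function(x, ...) {
  graphics::plot(x$curve$temps_C, x$curve$absorbance, pch = 16, cex = 0.4,
                 xlab = "Temperature (degC)", ylab = "A260 (AU)",
                 main = sprintf("%s, ct = %.3g M", x$curve$duplex_id, x$curve$ct), ...)
  if (x$converged) {
    tt <- seq(min(x$curve$temps_C), max(x$curve$temps_C), length.out = 200)
    graphics::lines(tt, predict(x, tt), col = 2, lwd = 2)
    graphics::abline(x$baseline_ss["intercept"], x$baseline_ss["slope"],
                     lty = 3, col = "grey40")
    graphics::abline(x$baseline_ds["intercept"], x$baseline_ds["slope"],
                     lty = 3, col = "grey40")
    graphics::abline(v = x$tm_C, lty = 2, col = 4)
  }
  invisible(x)
}

#' @export
simulate.melt_fit <- function(object, nsim = 1, seed = NULL, noise_sd = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- object$rms_residual
  base <- predict(object)
  lapply(seq_len(nsim), function(i)
    melt_curve(object$curve$temps_C,
               base + stats::rnorm(length(base), 0, noise_sd),
               object$curve$ct,
               duplex_id = object$curve$duplex_id,
               run_id = paste0("sim", i)))
}

#' Average individual curve fits
#'
#' Per-parameter mean and sample standard deviation (n-1 denominator) over a
#' set of converged two-state fits. `dG37` is averaged over the per-curve
#' `dG37` values, not recomputed from the averaged `dH`/`dS` -- the
#' "average of curve fits" reporting convention.
#'
#' @param fits list of [fit_melt_curve()] results (non-converged fits are
#'   dropped with a message; at least 2 converged fits are required).
#' @return object of class `thermo_params`: formation-signed `dH`, `dS`,
#'   `dG37` with sample SDs, `tm_C` (mean of per-curve Tm at 1e-4 M), `n`,
#'   and `source = "curve_fit_average"`.
#' @export
average_curve_fits <- function(fits) {
  if (inherits(fits, "melt_fit")) fits <- list(fits)
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) < length(fits))
    message(length(fits) - length(conv), " non-converged fit(s) dropped")
  if (length(conv) < 2)
    stop("need at least 2 converged fits to average, got ", length(conv))
  dH <- vapply(conv, `[[`, numeric(1), "dH")
  dS <- vapply(conv, `[[`, numeric(1), "dS")
  dG <- vapply(conv, `[[`, numeric(1), "dG37")
  tm <- tm_at_concentration(dH, dS, 1e-4)
  thermo_params(dH = mean(dH), dS = mean(dS), dG37 = mean(dG),
                sd_dH = stats::sd(dH), sd_dS = stats::sd(dS),
                sd_dG37 = stats::sd(dG),
                tm_C = mean(tm), n = length(conv),
                source = "curve_fit_average")
}

#' Thermodynamic parameter set for one duplex
#'
#' The currency of the reported thermodynamic tables: formation-signed
#' `dH` (kcal/mol), `dS` (eu) and `dG37` (kcal/mol) with their sample
#' standard deviations, plus the melting temperature at 1e-4 M.
#'
#' When `dG37` is omitted it is derived as `dH - 310.15*dS/1000`. A warning
#' is raised if `dH` and `dS` disagree in sign.
#'
#' @param dH,dS,dG37 parameter values (formation-signed).
#' @param sd_dH,sd_dS,sd_dG37 sample standard deviations (`NA` if unknown).
#' @param tm_C melting temperature at 1e-4 M, degrees C (`NA` to derive).
#' @param n number of underlying observations.
#' @param source `"curve_fit_average"` or `"vant_hoff"`.
#' @return object of class `thermo_params`.
#' @export
thermo_params <- function(dH, dS, dG37 = NULL,
                          sd_dH = NA_real_, sd_dS = NA_real_,
                          sd_dG37 = NA_real_, tm_C = NA_real_,
                          n = NA_integer_,
                          source = c("curve_fit_average", "vant_hoff")) {
  source <- match.arg(source)
  if (is.null(dG37)) dG37 <- dg_at_temperature(dH, dS)
  if (sign(dH) != sign(dS))
    warning("dH and dS have opposite signs; two-state parameters normally agree in sign")
  if (!is.finite(tm_C)) tm_C <- tm_at_concentration(dH, dS, 1e-4)
  structure(list(dH = dH, dS = dS, dG37 = dG37,
                 sd_dH = sd_dH, sd_dS = sd_dS, sd_dG37 = sd_dG37,
                 tm_C = tm_C, n = n, source = source),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, digits = 2, ...) {
  fmt <- function(v, s, d) if (is.finite(s))
    sprintf("%.*f +/- %.*f", d, v, d, s) else sprintf("%.*f", d, v)
  cat(sprintf("Thermodynamic parameters (%s, n = %s)\n", x$source,
              ifelse(is.na(x$n), "?", x$n)))
  cat("  -dH   (kcal/mol):", fmt(-x$dH, x$sd_dH, 1), "\n")
  cat("  -dS   (eu)      :", fmt(-x$dS, x$sd_dS, 1), "\n")
  cat("  -dG37 (kcal/mol):", fmt(-x$dG37, x$sd_dG37, 2), "\n")
  cat("  Tm at 1e-4 M    :", sprintf("%.1f degC", x$tm_C), "\n")
  invisible(x)
}
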