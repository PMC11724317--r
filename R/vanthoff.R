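# Concentration-dependence route: ordinary least squares of 1/Tm on
# ln(ct/4); dH = R/slope, dS = dH * intercept * 1000.

#' van't Hoff fit of melting-temperature concentration dependence
#'
#' Ordinary least squares of `1/Tm` (K^-1) on `ln(ct/4)` for a
#' non-self-complementary duplex:
#' `1/Tm = (dS/(1000*dH)) + (R/(1000*dH)) * ln(ct/4)`,
#' so `dH = R/(1000*slope)` kcal/mol and `dS = 1000*intercept*dH` eu.
#' Standard deviations of `dH`, `dS` and `dG37` are propagated from the
#' regression coefficient covariance by the delta method.
#'
#' @param ct total strand concentrations, mol/L (at least 3 distinct values;
#'   duplicated concentrations are collapsed by averaging `1/Tm`, with a
#'   warning).
#' @param tm melting temperatures, same length as `ct`.
#' @param tm_unit `"C"` (default) or `"K"`.
#' @param self_complementary use `ln(ct)` instead of `ln(ct/4)`.
#' @return object of class `vant_hoff`: `slope`, `intercept`, `r_squared`,
#'   `n_points`, the underlying `lm` fit, and a [thermo_params()] in
#'   `$params` (source `"vant_hoff"`).
#' @examples
#' ct <- 10^seq(-6, -4, length.out = 9)
#' tm <- tm_at_concentration(-67.6, -187.0, ct)
#' vant_hoff(ct, tm)
#' @export
vant_hoff <- function(ct, tm, tm_unit = c("C", "K"),
                      self_complementary = FALSE) {
  tm_unit <- match.arg(tm_unit)
  stopifnot(length(ct) == length(tm), all(is.finite(ct)), all(is.finite(tm)),
            all(ct > 0))
  tm_K <- if (tm_unit == "C") tm + .KELVIN else tm
  if (any(tm_K <= 0)) stop("non-physical melting temperature")
  if (anyDuplicated(ct)) {
    warning("duplicate concentrations collapsed by averaging 1/Tm")
    inv <- tapply(1 / tm_K, ct, mean)
    ct <- as.numeric(names(inv))
    inv_tm <- as.numeric(inv)
  } else inv_tm <- 1 / tm_K
  if (length(ct) < 3)
    stop("need at least 3 distinct concentrations, got ", length(ct))

  x <- log(ct / if (self_complementary) 1 else 4)
  fit <- stats::lm(inv_tm ~ x)
  b <- stats::coef(fit)
  slope <- unname(b[2]); intercept <- unname(b[1])
  if (!is.finite(slope) || slope == 0)
    stop("zero or undefined slope: no concentration dependence")

  dH <- .RGAS / (1000 * slope)          # kcal/mol
  dS <- 1000 * intercept * dH           # eu
  dG37 <- dg_at_temperature(dH, dS)

  # delta-method SDs from the coefficient covariance (b0 = intercept, b1 = slope);
  # a noise-free regression triggers the harmless perfect-fit warning
  V <- suppressWarnings(stats::vcov(fit))
  g_dH <- c(0, -.RGAS / (1000 * slope^2))
  g_dS <- c(.RGAS / slope, -.RGAS * intercept / slope^2)
  g_dG <- g_dH - .T37 * g_dS / 1000
  sd_of <- function(g) sqrt(drop(t(g) %*% V %*% g))

  params <- thermo_params(dH = dH, dS = dS, dG37 = dG37,
                          sd_dH = sd_of(g_dH), sd_dS = sd_of(g_dS),
                          sd_dG37 = sd_of(g_dG),
                          n = length(ct), source = "vant_hoff")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_points = length(ct), lm = fit, params = params,
                 ct = ct, inv_tm = inv_tm,
                 self_complementary = self_complementary),
            class = "vant_hoff")
}

#' @export
print.vant_hoff <- function(x, ...) {
  cat(sprintf("van't Hoff fit: 1/Tm vs ln(ct/%d), %d points, R^2 = %.4f\n",
              if (x$self_complementary) 1L else 4L, x$n_points, x$r_squared))
  print(x$params)
  invisible(x)
}

#' @export
coef.vant_hoff <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept,
    dH = object$params$dH, dS = object$params$dS,
    dG37 = object$params$dG37)
}

#' @export
plot.vant_hoff <- function(x, ...) {
  xx <- log(x$ct / if (x$self_complementary) 1 else 4)
  graphics::plot(xx, x$inv_tm, pch = 16,
                 xlab = "ln(ct/4)", ylab = "1/Tm (1/K)", ...)
  graphics::abline(x$intercept, x$slope, col = 2)
  invisible(x)
}
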