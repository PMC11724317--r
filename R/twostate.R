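# Two-state hybridization model for non-self-complementary duplexes:
#   2 single strands <-> duplex,  K(T) = exp(dS/R - dH/(R*T)),  dCp = 0.
# All enthalpies kcal/mol, entropies in eu (cal mol^-1 K^-1), formation-signed
# (negative for duplex formation). Temperatures Kelvin internally.

#' Physical constants used throughout
#'
#' Gas constant in cal mol^-1 K^-1, the Celsius offset, and the reporting
#' temperature for hybridization free energies (37 C = 310.15 K).
#' @keywords internal
#' @name duplexmelt-constants
NULL

.RGAS <- 1.9872      # cal mol^-1 K^-1
.KELVIN <- 273.15
.T37 <- 310.15       # K

#' Equilibrium constant of duplex formation at a temperature
#'
#' van't Hoff temperature dependence with no heat-capacity term:
#' `K(T) = exp(dS/R - 1000*dH/(R*T))`.
#'
#' @param dH formation enthalpy, kcal/mol (negative for duplex formation).
#' @param dS formation entropy, eu.
#' @param temp_K temperature(s) in Kelvin.
#' @return association constant(s), 1/M.
#' @export
k_twostate <- function(dH, dS, temp_K) {
  stopifnot(is.finite(dH), is.finite(dS), all(is.finite(temp_K)), all(temp_K > 0))
  exp(dS / .RGAS - 1000 * dH / (.RGAS * temp_K))
}

#' Fraction of strands in duplex form
#'
#' Closed-form root of the two-state mass balance for a non-self-complementary
#' duplex at total strand concentration `ct`: `K = 2f / ((1-f)^2 * ct)`, whose
#' root in \[0, 1\] is `f = ((a+1) - sqrt(2a+1))/a` with `a = K*ct`.
#' At the melting temperature `K(Tm) = 4/ct`, giving `f = 1/2`.
#'
#' @param K association constant(s), 1/M; vectorized.
#' @param ct total strand concentration, mol/L.
#' @return fraction(s) in \[0, 1\].
#' @export
fraction_duplex <- function(K, ct) {
  if (!all(is.finite(K)) || !is.finite(ct)) stop("'K' and 'ct' must be finite")
  if (any(K < 0)) stop("'K' must be >= 0")
  if (ct <= 0) stop("'ct' must be > 0")
  a <- K * ct
  # conjugate form of ((a+1) - sqrt(2a+1))/a: numerically stable for all
  # a >= 0 (the naive difference cancels catastrophically as a -> 0)
  f <- a / ((a + 1) + sqrt(2 * a + 1))
  pmin(pmax(f, 0), 1)
}

#' Hybridization free energy at a temperature
#'
#' `dG(T) = dH - T*dS/1000` in kcal/mol, the Table-style arithmetic evaluated
#' by default at 310.15 K.
#'
#' @param dH enthalpy, kcal/mol.
#' @param dS entropy, eu.
#' @param temp_K temperature in Kelvin (default 310.15).
#' @return free energy, kcal/mol. Vectorized over `dH`/`dS`.
#' @export
dg_at_temperature <- function(dH, dS, temp_K = .T37) {
  if (!all(is.finite(dH)) || !all(is.finite(dS)) || !all(is.finite(temp_K)))
    stop("inputs must be finite")
  dH - temp_K * dS / 1000
}

#' Melting temperature at a total strand concentration
#'
#' For a non-self-complementary duplex, `Tm(K) = 1000*dH / (dS + R*ln(ct/4))`
#' (all-cal arithmetic), returned in degrees Celsius. Self-complementary
#' duplexes use `ln(ct)` instead; the duplexes studied here are all
#' non-self-complementary.
#'
#' @param dH enthalpy, kcal/mol (same sign as `dS`, nonzero).
#' @param dS entropy, eu.
#' @param ct total strand concentration, mol/L (default 1e-4, the
#'   concentration used for reported melting temperatures).
#' @param self_complementary use the `ln(ct)` abscissa instead of `ln(ct/4)`.
#' @return melting temperature, degrees C. Vectorized over `dH`/`dS`.
#' @export
tm_at_concentration <- function(dH, dS, ct = 1e-4, self_complementary = FALSE) {
  if (!all(is.finite(dH)) || !all(is.finite(dS)) ||
      !all(is.finite(ct)) || any(ct <= 0))
    stop("inputs must be finite and ct > 0")
  if (any(dH == 0) || any(dS == 0) || any(sign(dH) != sign(dS)))
    stop("'dH' and 'dS' must be nonzero and of the same sign")
  denom <- dS + .RGAS * log(ct / if (self_complementary) 1 else 4)
  tm_K <- 1000 * dH / denom
  if (any(tm_K <= 0))
    stop("no physical melting temperature for these parameters at ct = ", ct)
  tm_K - .KELVIN
}

#' Two-state absorbance forward model
#'
#' Absorbance at 260 nm as the fraction-weighted mixture of linear single- and
#' double-strand baselines:
#' `A(T) = (1-f(T)) * (m_ss*T + b_ss) + f(T) * (m_ds*T + b_ds)`,
#' with `f(T)` from [fraction_duplex()] and temperatures in degrees C on the
#' baseline scale.
#'
#' @param dH,dS formation-signed thermodynamic parameters (kcal/mol, eu).
#' @param ct total strand concentration, mol/L.
#' @param temps_C temperatures, degrees C.
#' @param baselines numeric of length 4: `c(m_ss, b_ss, m_ds, b_ds)`
#'   (slopes AU/degC, intercepts AU).
#' @return absorbance values (AU), same length as `temps_C`.
#' @export
absorbance_twostate <- function(dH, dS, ct, temps_C,
                                baselines = c(0.0012, 0.95, 2e-4, 0.70)) {
  if (dH == 0) stop("'dH' must be nonzero: no transition")
  stopifnot(length(baselines) == 4, all(is.finite(baselines)),
            all(is.finite(temps_C)))
  f <- fraction_duplex(k_twostate(dH, dS, temps_C + .KELVIN), ct)
  ss <- baselines[1] * temps_C + baselines[2]
  ds <- baselines[3] * temps_C + baselines[4]
  (1 - f) * ss + f * ds
}

#' Construct a melting curve
#'
#' One absorbance-versus-temperature series at 260 nm with its total strand
#' concentration attached. Temperatures must be strictly increasing and the
#' series must hold at least 20 points.
#'
#' @param temps_C temperatures, degrees C, strictly increasing.
#' @param absorbance absorbance at 260 nm, AU, same length as `temps_C`.
#' @param ct total strand concentration, mol/L (> 0).
#' @param duplex_id identifier for the duplex.
#' @param run_id optional run label (dilution series bookkeeping).
#' @return an object of class `melt_curve`.
#' @export
melt_curve <- function(temps_C, absorbance, ct, duplex_id = "duplex",
                       run_id = NA_character_) {
  temps_C <- as.numeric(temps_C)
  absorbance <- as.numeric(absorbance)
  if (length(temps_C) != length(absorbance))
    stop("'temps_C' and 'absorbance' must have equal length")
  if (length(temps_C) < 20)
    stop("a melting curve needs at least 20 points, got ", length(temps_C))
  if (any(!is.finite(temps_C)) || any(!is.finite(absorbance)))
    stop("non-finite values in melting curve")
  if (any(diff(temps_C) <= 0))
    stop("temperatures must be strictly increasing")
  if (!is.finite(ct) || ct <= 0) stop("'ct' must be > 0")
  structure(list(duplex_id = as.character(duplex_id),
                 temps_C = temps_C, absorbance = absorbance,
                 ct = ct, run_id = run_id),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("Melting curve '%s': %d points, %.1f-%.1f degC, ct = %.3g M\n",
              x$duplex_id, length(x$temps_C), min(x$temps_C), max(x$temps_C),
              x$ct))
  invisible(x)
}

#' Simulate a melting curve from thermodynamic parameters
#'
#' Forward-models absorbance over a temperature grid via
#' [absorbance_twostate()] and returns a [melt_curve()], optionally with
#' i.i.d. Gaussian noise.
#'
#' @inheritParams absorbance_twostate
#' @param noise_sd Gaussian noise standard deviation, AU (0 = noise-free).
#' @param duplex_id,run_id passed to [melt_curve()].
#' @return a `melt_curve`.
#' @export
simulate_absorbance <- function(dH, dS, ct, temps_C = seq(0, 90, by = 0.5),
                                baselines = c(0.0012, 0.95, 2e-4, 0.70),
                                noise_sd = 0, duplex_id = "sim",
                                run_id = NA_character_) {
  A <- absorbance_twostate(dH, dS, ct, temps_C, baselines)
  if (noise_sd > 0) A <- A + stats::rnorm(length(A), 0, noise_sd)
  melt_curve(temps_C, A, ct, duplex_id = duplex_id, run_id = run_id)
}
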