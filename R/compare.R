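# Stability comparisons between modified duplexes and their unmodified
# references: ddG37 with propagated SDs, dTm, the two-state consistency
# check, and the predicted-vs-experimental correlation.

#' Free-energy difference against a reference duplex
#'
#' `ddG = dG_y - dG_ref` on formation-signed inputs, so a positive value
#' means the modification destabilizes the duplex.
#'
#' @param dg_y,dg_ref hybridization free energies, kcal/mol
#'   (formation-signed, i.e. negative). Vectorized.
#' @return kcal/mol.
#' @export
ddg <- function(dg_y, dg_ref) {
  stopifnot(all(is.finite(dg_y)), all(is.finite(dg_ref)))
  dg_y - dg_ref
}

#' Propagated standard deviation of a difference
#'
#' For independent quantities, `sd(a - b) = sqrt(sd_a^2 + sd_b^2)`.
#'
#' @param sd_a,sd_b standard deviations (>= 0). Vectorized.
#' @return propagated standard deviation.
#' @export
sd_propagate <- function(sd_a, sd_b) {
  if (any(sd_a < 0) || any(sd_b < 0)) stop("standard deviations must be >= 0")
  sqrt(sd_a^2 + sd_b^2)
}

#' Melting-temperature difference against a reference duplex
#'
#' @param tm_y,tm_ref melting temperatures, degrees C, both at the same
#'   total strand concentration (1e-4 M in the reported tables). Vectorized.
#' @return degrees C.
#' @export
delta_tm <- function(tm_y, tm_ref) {
  stopifnot(all(is.finite(tm_y)), all(is.finite(tm_ref)))
  tm_y - tm_ref
}

#' Two-state consistency check between the two analysis routes
#'
#' A duplex melts in a two-state manner when the enthalpy from the
#' concentration-dependence (van't Hoff) route agrees with that from
#' averaging individual curve fits: `pct = 100*|dh_vh - dh_avg|/|dh_avg|`
#' must not exceed the threshold (15% by convention).
#'
#' @param dh_vh,dh_avg enthalpies from the two routes, kcal/mol. Vectorized.
#' @param threshold_pct pass threshold, percent (default 15).
#' @return data.frame with columns `pct` and `pass`.
#' @export
two_state_check <- function(dh_vh, dh_avg, threshold_pct = 15) {
  stopifnot(all(is.finite(dh_vh)), all(is.finite(dh_avg)))
  if (any(dh_avg == 0)) stop("'dh_avg' must be nonzero")
  pct <- 100 * abs(dh_vh - dh_avg) / abs(dh_avg)
  data.frame(pct = pct, pass = pct <= threshold_pct)
}

#' Pearson correlation between measured and predicted stability changes
#'
#' Product-moment correlation over (ddG37, ddG_pred) pairs. Reference
#' duplexes contribute identically-zero pairs by construction; they are
#' excluded by default and can be kept with `include_references = TRUE`.
#'
#' @param ddg_exp,ddg_pred paired experimental and predicted free-energy
#'   differences, kcal/mol.
#' @param include_references keep pairs where both values are exactly zero.
#' @return Pearson r.
#' @export
pred_exp_correlation <- function(ddg_exp, ddg_pred, include_references = FALSE) {
  stopifnot(length(ddg_exp) == length(ddg_pred),
            all(is.finite(ddg_exp)), all(is.finite(ddg_pred)))
  if (!include_references) {
    keep <- !(ddg_exp == 0 & ddg_pred == 0)
    ddg_exp <- ddg_exp[keep]
    ddg_pred <- ddg_pred[keep]
  }
  if (length(ddg_exp) < 3) stop("need at least 3 pairs")
  if (stats::sd(ddg_exp) == 0 || stats::sd(ddg_pred) == 0)
    stop("zero variance in one of the coordinates")
  stats::cor(ddg_exp, ddg_pred)
}

#' Compare duplexes to their references
#'
#' Builds the comparison block of a thermodynamic table: for every duplex,
#' `ddG37` (with the propagated SD) and `dTm` against the reference duplex
#' named in `reference_map`. References compare to themselves with zeros.
#' Reference pairing is explicit -- each modified duplex is compared to the
#' unmodified duplex sharing its opposing residue -- and never inferred from
#' sequence strings.
#'
#' @param params data.frame with columns `duplex_id`, `dG37`, `sd_dG37`,
#'   `tm_C` (formation-signed free energies).
#' @param reference_map data.frame with columns `duplex_id`, `reference_id`.
#' @return data.frame with columns `duplex_id`, `reference_id`, `ddG37`,
#'   `sd_ddG37`, `dTm`.
#' @export
compare_duplexes <- function(params, reference_map) {
  need <- c("duplex_id", "dG37", "sd_dG37", "tm_C")
  if (!all(need %in% names(params)))
    stop("'params' must have columns ", paste(need, collapse = ", "))
  if (!all(c("duplex_id", "reference_id") %in% names(reference_map)))
    stop("'reference_map' must have columns duplex_id, reference_id")
  i <- match(params$duplex_id, reference_map$duplex_id)
  if (anyNA(i))
    stop("no reference mapping for: ",
         paste(params$duplex_id[is.na(i)], collapse = ", "))
  ref_id <- reference_map$reference_id[i]
  j <- match(ref_id, params$duplex_id)
  if (anyNA(j))
    stop("reference duplex absent from 'params': ",
         paste(unique(ref_id[is.na(j)]), collapse = ", "))
  data.frame(
    duplex_id = params$duplex_id,
    reference_id = ref_id,
    ddG37 = ddg(params$dG37, params$dG37[j]),
    sd_ddG37 = sd_propagate(params$sd_dG37, params$sd_dG37[j]),
    dTm = delta_tm(params$tm_C, params$tm_C[j]))
}
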