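# Aggregation of per-frame molecular-mechanics energy components into
# per-state predicted hybridization free energies and their comparisons.

.ENERGY_COLS <- c("frame", "state", "e_complex", "e_s1", "e_s2",
                  "g_nm_complex", "g_nm_s1", "g_nm_s2")

#' Read a per-frame energy-component table
#'
#' Delimited text with columns `frame`, `state`, `e_complex`, `e_s1`,
#' `e_s2` (molecular-mechanics + solvation totals of the duplex and the two
#' strands, kcal/mol) and `g_nm_complex`, `g_nm_s1`, `g_nm_s2` (normal-mode
#' vibrational/entropic free-energy terms). Strand terms are taken from the
#' same frame as the complex (single-trajectory decomposition).
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return validated data.frame.
#' @export
read_energy_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing <- setdiff(.ENERGY_COLS, names(df))
  if (length(missing))
    stop("energy table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  num <- setdiff(.ENERGY_COLS, "state")
  for (cl in num) {
    if (!is.numeric(df[[cl]]) || any(!is.finite(df[[cl]])))
      stop("non-numeric or non-finite values in column '", cl, "' of ", path)
  }
  df
}

#' Aggregate frame energies into per-state predicted free energies
#'
#' Per conformational state:
#' `dG_rism  = <E_complex - E_strand1 - E_strand2>`,
#' `dG_nmode = <G_nm_complex - G_nm_strand1 - G_nm_strand2>`, and
#' `dG_pred  = dG_rism - dG_nmode`
#' (the normal-mode term enters with a minus sign exactly as defined; no
#' hidden re-signing).
#'
#' @param frames data.frame with the columns of [read_energy_table()].
#' @param states states to aggregate (default: all present, in order of
#'   first appearance).
#' @return data.frame of class `energy_states` with columns `state`,
#'   `n_frames`, `dG_rism`, `dG_nmode`, `dG_pred`.
#' @export
aggregate_state <- function(frames, states = unique(frames$state)) {
  missing <- setdiff(.ENERGY_COLS, names(frames))
  if (length(missing))
    stop("frame table lacks column(s): ", paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(states, function(s) {
    fr <- frames[frames$state == s, , drop = FALSE]
    if (!nrow(fr)) stop("no frames for state '", s, "'")
    rism <- mean(fr$e_complex - fr$e_s1 - fr$e_s2)
    nmode <- mean(fr$g_nm_complex - fr$g_nm_s1 - fr$g_nm_s2)
    data.frame(state = s, n_frames = nrow(fr),
               dG_rism = rism, dG_nmode = nmode, dG_pred = rism - nmode)
  }))
  class(out) <- c("energy_states", class(out))
  out
}

#' Predicted stability change against a reference state or duplex
#'
#' `ddG_pred = dG_pred - dG_pred(reference)`.
#'
#' @param dg_pred predicted free energy (or vector), kcal/mol.
#' @param dg_pred_ref reference predicted free energy, kcal/mol.
#' @return kcal/mol.
#' @export
ddg_pred <- function(dg_pred, dg_pred_ref) {
  stopifnot(all(is.finite(dg_pred)), all(is.finite(dg_pred_ref)))
  dg_pred - dg_pred_ref
}

#' Global-minimum conformational state
#'
#' The state with minimal `dG_pred`; states within `tie_window` kcal/mol of
#' the minimum (2.5 by default) are reported as co-populated alternates.
#'
#' @param states an `energy_states` data.frame from [aggregate_state()].
#' @param tie_window alternate-state window, kcal/mol.
#' @return list with `minimum` (one-row data.frame) and `alternates`
#'   (possibly empty data.frame of other states inside the window).
#' @export
global_minimum <- function(states, tie_window = 2.5) {
  if (!nrow(states)) stop("no states")
  i <- which.min(states$dG_pred)
  alt <- states[-i, , drop = FALSE]
  alt <- alt[alt$dG_pred - states$dG_pred[i] <= tie_window, , drop = FALSE]
  list(minimum = states[i, , drop = FALSE], alternates = alt)
}

#' Overstabilization of a prediction relative to experiment
#'
#' `ddG_exp - ddG_pred`: by how much the energy model overstabilizes
#' (positive values) the modified duplex relative to what was measured.
#'
#' @param ddg_exp experimental stability change, kcal/mol.
#' @param ddg_pred predicted stability change, kcal/mol.
#' @return kcal/mol. Vectorized.
#' @export
overstabilization <- function(ddg_exp, ddg_pred) {
  stopifnot(all(is.finite(ddg_exp)), all(is.finite(ddg_pred)))
  ddg_exp - ddg_pred
}
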