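# Readers and writers: delimited melting curves with a manifest, multi-model
# PDB coordinate frames, the packaged reference tables for the sixteen
# studied duplexes, and printed-precision report formatting.

#' Read melting curves via a manifest
#'
#' The manifest is delimited text with columns `file`, `duplex_id`,
#' `ct_molar` and (optionally) `run_id`; each referenced file holds two
#' columns `temperature_C` and `absorbance`. Validation is strict: missing
#' files, non-numeric cells and non-increasing temperatures are errors that
#' name the file (and line where known), never silent coercions.
#'
#' @param manifest_path path to the manifest.
#' @param sep field separator (default tab).
#' @return list of [melt_curve()] objects.
#' @export
read_melt_curves <- function(manifest_path, sep = "\t") {
  if (!file.exists(manifest_path)) stop("no such manifest: ", manifest_path)
  man <- utils::read.table(manifest_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("file", "duplex_id", "ct_molar")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (!"run_id" %in% names(man)) man$run_id <- NA_character_
  dir <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(dir, man$file[i])
    if (!file.exists(path))
      stop("manifest row ", i, ": no such curve file: ", path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!all(c("temperature_C", "absorbance") %in% names(df)))
      stop(path, ": curve files need columns temperature_C, absorbance")
    tv <- suppressWarnings(as.numeric(df$temperature_C))
    av <- suppressWarnings(as.numeric(df$absorbance))
    bad <- which(!is.finite(tv) | !is.finite(av))
    if (length(bad))
      stop(path, ": non-numeric cell at data line ", bad[1])
    ct <- suppressWarnings(as.numeric(man$ct_molar[i]))
    if (!is.finite(ct) || ct <= 0)
      stop("manifest row ", i, ": invalid ct_molar '", man$ct_molar[i], "'")
    tryCatch(
      melt_curve(tv, av, ct, duplex_id = man$duplex_id[i],
                 run_id = man$run_id[i]),
      error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE))
  })
}

#' Read coordinate frames from a multi-model PDB file
#'
#' Uses the standard PDB reader (MODEL/ENDMDL records become frames) and
#' maps residue names through the modified-residue alias table (`7A`, `AL`,
#' `7AL` are kept as-is; unknown names are an error). Atom ordering must be
#' identical across models.
#'
#' @param path PDB file path.
#' @param residue_alias optional named character vector remapping PDB
#'   residue names to the codes used here (e.g. `c(ADE = "A")`). Built-in:
#'   `A/C/G/U` one-letter names and `7A`, `AL`, `7AL`.
#' @return a [frame_set()].
#' @export
read_frames <- function(path, residue_alias = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  resid <- trimws(at$resid)
  if (!is.null(residue_alias)) {
    hit <- resid %in% names(residue_alias)
    resid[hit] <- residue_alias[resid[hit]]
  }
  unknown <- setdiff(unique(resid), .KNOWN_RESIDUES)
  if (length(unknown))
    stop("unknown residue name(s) in ", path, ": ",
         paste(unknown, collapse = ", "),
         " (supply 'residue_alias' to remap)")
  nmod <- nrow(pdb$xyz)
  na <- nrow(at)
  if (ncol(pdb$xyz) != 3 * na)
    stop("atom count mismatch across models in ", path)
  coords <- array(NA_real_, c(na, 3, nmod))
  for (m in seq_len(nmod))
    coords[, , m] <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
  atoms <- data.frame(elety = trimws(at$elety), resid = resid,
                      resno = at$resno, chain = at$chain)
  frame_set(coords, atoms, provenance = path)
}

#' Write coordinate frames as a multi-model PDB file
#'
#' Fixed-width ATOM records wrapped in MODEL/ENDMDL blocks, one model per
#' frame, readable back by [read_frames()].
#'
#' @param fs a [frame_set()].
#' @param path output path.
#' @param frames frame indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_frames <- function(fs, path, frames = seq_len(n_frames(fs))) {
  at <- fs$atoms
  elem <- substr(gsub("[^A-Za-z].*$", "", at$elety), 1, 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    f <- frames[m]
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- fs$coords[, , f]
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), at$elety, at$resid, at$chain, at$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, elem)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Packaged thermodynamic reference table for the sixteen studied duplexes
#'
#' The published two-state melting parameters of the 9-mer duplexes carrying
#' a central `X:Y` pair (`X` = A, 7A, A^L, 7A^L; `Y` = A, C, G, U): the
#' curve-fit-average block and the 1/Tm-versus-ln(ct/4) block (each `dH`,
#' `dS`, `dG37` with sample SDs and the melting temperature at 1e-4 M),
#' plus the published comparison columns (`ddG37`, its propagated SD,
#' `dTm`) and the reference pairing. Energies are returned formation-signed
#' (negative); the printed table reports magnitudes. The `vh_consistent`
#' flag marks the one row (A-U, concentration-plot block) whose printed
#' `dH`/`dS` do not reproduce its printed `dG37`/`Tm`, a documented
#' internal inconsistency excluded from exact-match checks.
#'
#' @return data.frame, one row per duplex.
#' @export
duplex_thermo_table <- function() {
  path <- system.file("extdata", "duplex_thermo.tsv", package = "duplexmelt",
                      mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (cl in grep("^(dh|ds|dg37)_", names(df), value = TRUE))
    if (!startsWith(cl, "sd_")) df[[cl]] <- -df[[cl]]
  df
}

#' Packaged predicted-energetics reference table for the twelve modelled duplexes
#'
#' Published middle-pair energetics of the modelled systems: experimental
#' `ddG37` (concentration-plot route), predicted hybridization free energy
#' `dG_pred = dG_rism - dG_nmode`, its difference to the unmodified
#' reference (`ddG_pred`), the predicted and NMR loop orientations, and the
#' mean middle-pair hydrogen-bond count.
#'
#' @return data.frame, one row per modelled duplex.
#' @export
duplex_energy_table <- function() {
  path <- system.file("extdata", "duplex_energy.tsv", package = "duplexmelt",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = c("NA", ""),
                    stringsAsFactors = FALSE)
}

.fmt_sd <- function(v, s, d) ifelse(is.finite(s),
                                    sprintf("%.*f +/- %.*f", d, v, d, s),
                                    sprintf("%.*f", d, v))

#' Format a thermodynamic report at printed precision
#'
#' Tab-separated text in the published column order (curve-fit-average
#' block, concentration-plot block, comparison block), printing magnitudes
#' with one decimal for `dH`/`dS`/`Tm` and two decimals for free energies.
#' A full-precision machine-readable companion can be written alongside.
#'
#' @param tab data.frame in the layout of [duplex_thermo_table()]
#'   (formation-signed energies).
#' @param path optional output path for the formatted report.
#' @param full_precision_path optional path for the unrounded companion.
#' @return the formatted lines, invisibly.
#' @export
report_thermo_table <- function(tab, path = NULL, full_precision_path = NULL) {
  hdr <- paste(c("duplex", "-dH_fit", "-dS_fit", "-dG37_fit", "Tm_fit",
                 "-dH_vh", "-dS_vh", "-dG37_vh", "Tm_vh",
                 "ddG37", "dTm"), collapse = "\t")
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    paste(c(r$duplex_id,
            .fmt_sd(-r$dh_avg, r$sd_dh_avg, 1),
            .fmt_sd(-r$ds_avg, r$sd_ds_avg, 1),
            .fmt_sd(-r$dg37_avg, r$sd_dg37_avg, 2),
            sprintf("%.1f", r$tm_avg),
            .fmt_sd(-r$dh_vh, r$sd_dh_vh, 1),
            .fmt_sd(-r$ds_vh, r$sd_ds_vh, 1),
            .fmt_sd(-r$dg37_vh, r$sd_dg37_vh, 2),
            sprintf("%.1f", r$tm_vh),
            .fmt_sd(r$ddg37, r$sd_ddg37, 2),
            sprintf("%.1f", r$dtm)), collapse = "\t")
  }, character(1))
  out <- c(hdr, rows)
  if (!is.null(path)) writeLines(out, path)
  if (!is.null(full_precision_path))
    utils::write.table(tab, full_precision_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(out)
}
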