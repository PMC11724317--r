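# Nearest-neighbour extinction coefficients at 260 nm and Beer-Lambert
# strand concentrations.

# Standard single-strand RNA values (M^-1 cm^-1, 260 nm, 25 C): monomer
# coefficients and nearest-neighbour dimer coefficients of the classic
# oligonucleotide hypochromicity tables.
.EXT_MONO <- c(A = 15340, C = 7600, G = 12160, U = 10210)
.EXT_DIMER <- c(
  AA = 13650, AC = 10670, AG = 12790, AU = 12140,
  CA = 10670, CC = 7520,  CG = 9390,  CU = 8370,
  GA = 12920, GC = 9190,  GG = 11430, GU = 10960,
  UA = 12520, UC = 8900,  UG = 10400, UU = 10110)

# Modified residues with no published coefficients are approximated by the
# parent base; the approximation is reported with a warning.
.EXT_ALIAS <- c("7A" = "A", "AL" = "A", "7AL" = "A")

#' Embedded nearest-neighbour extinction table
#'
#' Returns the packaged 260 nm monomer and dimer molar extinction
#' coefficients (M^-1 cm^-1) used by [extinction_nn()].
#'
#' @return list with elements `monomer` and `dimer` (named numerics) and
#'   `alias` (modified-residue aliases).
#' @export
extinction_table <- function() {
  list(monomer = .EXT_MONO, dimer = .EXT_DIMER, alias = .EXT_ALIAS)
}

.normalize_residues <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 1 &&
      !grepl("[^ACGU]", sequence))
    sequence <- strsplit(sequence, "")[[1]]
  as.character(sequence)
}

#' Nearest-neighbour extinction coefficient of a single strand
#'
#' `eps = sum_i 2*eps(pair i, i+1) - sum_{i=2}^{n-1} eps(monomer i)` over the
#' embedded 260 nm table. Residues are given as a character vector of codes
#' (`"A"`, `"C"`, `"G"`, `"U"`, and the modified codes `"7A"`, `"AL"`,
#' `"7AL"`, which alias to `"A"` with a warning), or as a plain string of
#' one-letter codes.
#'
#' @param sequence residue codes, 5' to 3'.
#' @param table extinction table, as from [extinction_table()].
#' @return molar extinction coefficient, M^-1 cm^-1.
#' @export
extinction_nn <- function(sequence, table = extinction_table()) {
  res <- .normalize_residues(sequence)
  if (length(res) < 1) stop("empty sequence")
  aliased <- res %in% names(table$alias)
  if (any(aliased)) {
    warning("no extinction coefficients for modified residue(s) ",
            paste(unique(res[aliased]), collapse = ", "),
            "; using the parent base approximation")
    res[aliased] <- table$alias[res[aliased]]
  }
  unknown <- setdiff(res, names(table$monomer))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unique(unknown), collapse = ", "))
  n <- length(res)
  if (n == 1) return(unname(table$monomer[res]))
  pairs <- paste0(res[-n], res[-1])
  missing_pairs <- setdiff(pairs, names(table$dimer))
  if (length(missing_pairs))
    stop("missing dimer coefficient(s): ",
         paste(unique(missing_pairs), collapse = ", "))
  unname(2 * sum(table$dimer[pairs]) - sum(table$monomer[res[-c(1, n)]]))
}

#' Strand concentration from absorbance (Beer-Lambert)
#'
#' `c = A / (eps * path)`, used with the absorbance measured at 80 C where
#' the strands are single-stranded.
#'
#' @param absorbance absorbance, AU (> 0).
#' @param epsilon molar extinction coefficient, M^-1 cm^-1 (> 0).
#' @param path optical path length, cm (default 1).
#' @return concentration, mol/L.
#' @export
strand_concentration <- function(absorbance, epsilon, path = 1) {
  if (!all(is.finite(c(absorbance, epsilon, path))) ||
      any(absorbance <= 0) || any(epsilon <= 0) || path <= 0)
    stop("'absorbance', 'epsilon' and 'path' must be finite and > 0")
  absorbance / (epsilon * path)
}
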