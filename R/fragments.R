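#' The nine nucleic acid fragment ion series
#'
#' 5' series (`a-B`, `a`, `b`, `c`, `d`) and 3' series (`w`, `x`, `y`,
#' `z`), in the standard nomenclature for nucleic acid fragmentation.
#' @format Character vector of length 9.
#' @export
ION_TYPES <- c("a-B", "a", "b", "c", "d", "w", "x", "y", "z")

FIVE_PRIME_IONS <- c("a-B", "a", "b", "c", "d")
THREE_PRIME_IONS <- c("w", "x", "y", "z")

.base_shift_cache <- new.env(parent = emptyenv())

## mass of the base-located portion of a modification's shift (memoized)
mod_base_shift_mass <- function(code, placement) {
  key <- paste0(code, "\r", placement)
  v <- .base_shift_cache[[key]]
  if (is.null(v)) {
    v <- formula_mass(mod_base_shift_formula(code, placement))
    .base_shift_cache[[key]] <- v
  }
  v
}

## Neutral masses of all 9 ion series for every cleavage index, as an
## (n-1) x 9 matrix. Offset conventions follow the standard oligonucleotide
## calculators (McLuckey nomenclature):
##   c_i: 5' fragment of i residues, parent 5' terminus, 3'-phosphate
##   d = c + H2O;  b = c - HPO3;  a = b - H2O;  a-B = a - base(i)
##   w_j: 3' fragment of j residues, parent 3' terminus, 5'-phosphate
##   x = w - H2O;  y = w - HPO3;  z = y - H2O
## The base subtracted for a-B includes the base-located part of any
## modification at the cleavage-site residue (sugar-located parts remain).
fragment_mass_table <- function(seq) {
  n <- length(seq$residues)
  if (n < 2) stop("sequence must have at least 2 residues to fragment")
  water <- mass_constants[["water"]]; hpo3 <- mass_constants[["hpo3"]]
  res_mass <- unname(.nucleoside_masses[seq$residues])
  base_mass <- unname(.base_masses[seq$residues])
  for (i in which(!is.na(seq$mod_code))) {
    res_mass[i] <- res_mass[i] + mod_mass_shift(seq$mod_code[i])
    base_mass[i] <- base_mass[i] +
      mod_base_shift_mass(seq$mod_code[i], seq$mod_placement[i])
  }
  link <- hpo3 - water
  idx <- seq_len(n - 1L)
  fp_adj <- if (seq$five_prime == "phosphate") hpo3 else 0
  tp_adj <- switch(seq$three_prime, OH = 0, phosphate = hpo3,
                   cyclic_phosphate = hpo3 - water)
  c_ser <- cumsum(res_mass)[idx] + (idx - 1L) * link + fp_adj + hpo3
  d_ser <- c_ser + water
  b_ser <- c_ser - hpo3
  a_ser <- b_ser - water
  ab_ser <- a_ser - base_mass[idx]
  w_ser <- cumsum(rev(res_mass))[idx] + (idx - 1L) * link + hpo3 + tp_adj
  x_ser <- w_ser - water
  y_ser <- w_ser - hpo3
  z_ser <- y_ser - water
  cbind(`a-B` = ab_ser, a = a_ser, b = b_ser, c = c_ser, d = d_ser,
        w = w_ser, x = x_ser, y = y_ser, z = z_ser)
}

#' Neutral mass of a single theoretical fragment
#'
#' 5' series (a-B, a, b, c, d) count cleavage positions from the 5' end;
#' 3' series (w, x, y, z) from the 3' end. The a-B ion additionally loses
#' the nucleobase of the cleavage-site residue, including any base-located
#' modification mass (sugar-located modification mass is retained), which is
#' what makes a-B ions diagnostic for base- versus ribose-located
#' modifications.
#'
#' @param seq An `na_sequence` (or bracket-notation string).
#' @param ion_type One of `"a-B"`, `"a"`, `"b"`, `"c"`, `"d"`, `"w"`,
#'   `"x"`, `"y"`, `"z"`.
#' @param index Cleavage index, 1 to `length(seq) - 1`.
#' @return Neutral fragment mass in Da.
#' @export
fragment_neutral_mass <- function(seq, ion_type, index) {
  if (is.character(seq)) seq <- parse_sequence(seq)
  ion_type <- match.arg(ion_type, ION_TYPES)
  n <- length(seq$residues)
  if (index < 1 || index > n - 1) {
    stop("cleavage index must be in 1..", n - 1)
  }
  unname(fragment_mass_table(seq)[index, ion_type])
}

#' Generate the theoretical spectrum of an oligonucleotide
#'
#' One fragment per (ion type, cleavage index, charge), sorted by m/z.
#'
#' @param seq An `na_sequence` (or string).
#' @param ion_types Subset of the nine ion series to generate.
#' @param charges Negative integer fragment charges, e.g. `-1:-2`.
#' @return A data frame with columns `ion_type`, `index`, `charge`,
#'   `neutral_mass`, `mz`, sorted by `mz`.
#' @export
generate_theoretical_spectrum <- function(seq, ion_types = ION_TYPES,
                                          charges = -1L) {
  if (is.character(seq)) seq <- parse_sequence(seq)
  if (!length(ion_types)) stop("at least one ion type is required")
  ion_types <- match.arg(ion_types, ION_TYPES, several.ok = TRUE)
  if (any(charges >= 0)) stop("fragment charges must be negative")
  tab <- fragment_mass_table(seq)[, ion_types, drop = FALSE]
  n_idx <- nrow(tab); n_types <- ncol(tab)
  neutral <- as.vector(tab)                       # column-major: type blocks
  ion_type <- rep(colnames(tab), each = n_idx)
  index <- rep(seq_len(n_idx), times = n_types)
  out <- do.call(rbind, lapply(charges, function(z) {
    data.frame(ion_type = ion_type, index = index, charge = z,
               neutral_mass = neutral, mz = mz_from_mass(neutral, z),
               stringsAsFactors = FALSE)
  }))
  out[order(out$mz), , drop = FALSE]
}
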