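## Monoisotopic atomic masses (CODATA / AME2020), Da.
.ELEMENT_MASSES <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668
)

#' Physical constants used for mass bookkeeping
#'
#' `proton` is used to convert between neutral mass and m/z of deprotonated
#' ions; `neutron` is used for isotopologue precursor-offset correction;
#' `c13_spacing` (the C13-C12 mass difference) is the peak spacing used when
#' deisotoping fragment envelopes. These are physically distinct quantities
#' and are kept separate on purpose.
#'
#' @format A named numeric vector with elements `proton`, `neutron`,
#'   `c13_spacing`, `water`, `hpo3`.
#' @export
mass_constants <- c(
  proton      = 1.007276,
  neutron     = 1.008665,
  c13_spacing = 1.00335,
  water       = 18.01056468374,
  hpo3        = 79.96633052087
)

#' Create a chemical formula
#'
#' A chemical formula is represented as a named integer vector of element
#' counts. Negative counts are allowed so that difference formulas (e.g. the
#' mass shift of a modification) can be expressed.
#'
#' @param x A formula string such as `"C9H13N3O5"` or `"CH2"`; negative
#'   counts are written like `"O-1H-1N-1"`. Alternatively a named numeric
#'   vector of element counts, or another `chem_formula`.
#' @return A `chem_formula` object.
#' @examples
#' chem_formula("H2O")
#' chem_formula("CH2") + chem_formula("O")
#' @export
chem_formula <- function(x = character()) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.numeric(x)) {
    counts <- x
  } else if (is.character(x)) {
    counts <- c(C = 0)[0]
    if (length(x) == 1L && nzchar(x)) {
      matches <- gregexpr("([A-Z][a-z]?)(-?[0-9]*)", x, perl = TRUE)[[1]]
      parts <- regmatches(x, gregexpr("([A-Z][a-z]?)(-?[0-9]*)", x, perl = TRUE))[[1]]
      if (sum(nchar(parts)) != nchar(x)) {
        stop("cannot parse chemical formula: '", x, "'")
      }
      els <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
      ns <- sub("^[A-Z][a-z]?", "", parts)
      counts <- stats::setNames(ifelse(ns == "", 1L, suppressWarnings(as.integer(ns))), els)
      if (anyNA(counts)) stop("cannot parse chemical formula: '", x, "'")
    }
  } else {
    stop("cannot construct a chem_formula from class ", class(x)[1])
  }
  bad <- setdiff(names(counts), names(.ELEMENT_MASSES))
  if (length(bad)) {
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "))
  }
  counts <- tapply(as.numeric(counts), names(counts), sum)
  counts <- counts[counts != 0]
  out <- stats::setNames(as.integer(counts), names(counts))
  # canonical element order for printing / comparison
  ord <- order(match(names(out), names(.ELEMENT_MASSES)))
  structure(out[ord], class = "chem_formula")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format_formula(x), "  (", sprintf("%.5f", formula_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' Format a chemical formula as a string
#' @param x A `chem_formula`.
#' @return A single string, e.g. `"C9H13N3O5"`; empty formula gives `""`.
#' @export
format_formula <- function(x) {
  x <- chem_formula(x)
  if (!length(x)) return("")
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
`+.chem_formula` <- function(e1, e2) {
  a <- chem_formula(e1); b <- chem_formula(e2)
  chem_formula(c(stats::setNames(as.numeric(a), names(a)),
                 stats::setNames(as.numeric(b), names(b))))
}

#' @export
`-.chem_formula` <- function(e1, e2) {
  if (missing(e2)) return(chem_formula(stats::setNames(-as.numeric(e1), names(e1))))
  a <- chem_formula(e1); b <- chem_formula(e2)
  chem_formula(c(stats::setNames(as.numeric(a), names(a)),
                 stats::setNames(-as.numeric(b), names(b))))
}

#' Multiply a formula by an integer
#' @param x A `chem_formula`. @param n Integer multiplier (may be negative).
#' @return A `chem_formula`.
#' @export
formula_multiply <- function(x, n) {
  x <- chem_formula(x)
  chem_formula(stats::setNames(as.numeric(x) * n, names(x)))
}

#' Monoisotopic mass of a chemical formula
#'
#' @param formula A `chem_formula`, or anything `chem_formula()` accepts.
#' @return Monoisotopic mass in Da (can be negative for difference formulas).
#' @examples
#' formula_mass("H2O")   # 18.01056
#' formula_mass("CH2")   # 14.01565 (a methylation shift)
#' @export
formula_mass <- function(formula) {
  f <- chem_formula(formula)
  if (!length(f)) return(0.0)
  sum(.ELEMENT_MASSES[names(f)] * as.numeric(f))
}

#' Convert a neutral mass to m/z in negative ion mode
#'
#' Oligonucleotides ionize by deprotonation, so for charge z (a negative
#' integer) m/z = (M - |z| * m_proton) / |z|.
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param charge Negative integer charge (z <= -1).
#' @return m/z in Thomson.
#' @export
mz_from_mass <- function(mass, charge) {
  if (any(charge >= 0)) stop("negative ion mode only: charge must be <= -1")
  z <- abs(charge)
  (mass - z * mass_constants[["proton"]]) / z
}

#' Convert an observed m/z back to neutral mass
#' @param mz Observed m/z. @param charge Negative integer charge.
#' @return Neutral monoisotopic mass in Da.
#' @export
mass_from_mz <- function(mz, charge) {
  if (any(charge >= 0)) stop("negative ion mode only: charge must be <= -1")
  z <- abs(charge)
  mz * z + z * mass_constants[["proton"]]
}

#' Neutral mass shift of a salt adduct
#'
#' A salt adduct is one or more cations (Na+, K+) replacing backbone protons,
#' so the neutral mass shift is m(cations) - n * m(H) where n is the total
#' positive charge carried by the cations.
#'
#' @param adduct_formula Cation composition as a `chem_formula` (e.g. `"Na"`,
#'   `"K"`, `"NaK"`, `"Na2K"`).
#' @param cation_charge Total positive charge of the cations; defaults to the
#'   total cation atom count (each Na/K carries +1).
#' @return Mass shift in Da.
#' @examples
#' adduct_mass_shift("Na")  # 21.98194
#' adduct_mass_shift("K")   # 37.95588
#' @export
adduct_mass_shift <- function(adduct_formula, cation_charge = NULL) {
  f <- chem_formula(adduct_formula)
  bad <- setdiff(names(f), c("Na", "K"))
  if (length(bad)) stop("unsupported adduct cation(s): ", paste(bad, collapse = ", "))
  n <- sum(as.numeric(f))
  if (n <= 0) stop("adduct must contain at least one cation")
  if (is.null(cation_charge)) cation_charge <- n
  if (cation_charge <= 0) stop("cation charge must be positive")
  formula_mass(f) - cation_charge * .ELEMENT_MASSES[["H"]]
}
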