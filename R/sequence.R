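#' Construct an RNA oligonucleotide sequence
#'
#' The central analyte representation: canonical residues, per-position
#' modifications (at most one per position) with a resolved placement, and
#' the 5'/3' terminus chemistry.
#'
#' @param residues Character vector of canonical residue codes (A/C/G/U).
#' @param mod_code Character vector (same length) of modification search
#'   codes, `NA` where unmodified.
#' @param mod_placement Resolved placement per position: `"base"`,
#'   `"sugar"`, or `"split"`; `NA` where unmodified. Defaults to the registry
#'   placement (an `either` modification must be resolved explicitly).
#' @param five_prime `"OH"` or `"phosphate"`.
#' @param three_prime `"OH"`, `"phosphate"` or `"cyclic_phosphate"`.
#' @return An `na_sequence` object.
#' @seealso [parse_sequence()] for the bracket notation used in printed
#'   sequences, e.g. `"UAAC[m5C]CAAUGp"`.
#' @export
na_sequence <- function(residues, mod_code = rep(NA_character_, length(residues)),
                        mod_placement = NULL,
                        five_prime = "OH", three_prime = "OH") {
  residues <- as.character(residues)
  n <- length(residues)
  if (n < 1) stop("sequence must contain at least one residue")
  if (!all(residues %in% c("A", "C", "G", "U"))) {
    stop("illegal residue code(s): ",
         paste(unique(setdiff(residues, c("A", "C", "G", "U"))), collapse = ", "))
  }
  if (length(mod_code) != n) stop("mod_code must have one entry per residue")
  if (is.null(mod_placement)) {
    mod_placement <- rep(NA_character_, n)
    for (i in which(!is.na(mod_code))) {
      pl <- mod_resolved_placements(mod_code[i])
      if (length(pl) > 1) {
        stop("modification '", mod_code[i],
             "' has ambiguous placement; resolve to 'base' or 'sugar'")
      }
      mod_placement[i] <- pl
    }
  }
  five_prime <- match.arg(five_prime, c("OH", "phosphate"))
  three_prime <- match.arg(three_prime, c("OH", "phosphate", "cyclic_phosphate"))
  for (i in which(!is.na(mod_code))) {
    row <- modification_registry(mod_code[i])
    targets <- strsplit(row$targets, ",", fixed = TRUE)[[1]]
    if (!residues[i] %in% targets) {
      stop("modification '", mod_code[i], "' cannot be placed on residue '",
           residues[i], "' (position ", i, ")")
    }
    if (is.na(mod_placement[i])) stop("modified position ", i, " lacks a placement")
  }
  structure(list(residues = residues, mod_code = as.character(mod_code),
                 mod_placement = as.character(mod_placement),
                 five_prime = five_prime, three_prime = three_prime),
            class = "na_sequence")
}

#' Parse the printed oligonucleotide notation
#'
#' Plain letters are unmodified residues; a bracketed registry code is a
#' modified residue occupying one position (its canonical identity comes
#' from the registry's target base), e.g. `"UAAC[m5C]CAAUG"`. For
#' placement-ambiguous codes a suffix selects the resolved placement:
#' `"[mC?/b]"` (base) or `"[mC?/s]"` (sugar); without a suffix the base
#' placement is taken. A trailing lowercase `p` denotes the 3'-phosphate
#' left by RNase cleavage; a leading `p` a 5'-phosphate; a trailing `>p` a
#' 2',3'-cyclic phosphate.
#'
#' @param x Sequence string.
#' @return An `na_sequence`.
#' @examples
#' parse_sequence("UAAC[m5C]CAAUGp")
#' @export
parse_sequence <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- x
  five_prime <- "OH"; three_prime <- "OH"
  if (startsWith(s, "p")) { five_prime <- "phosphate"; s <- substring(s, 2) }
  if (endsWith(s, ">p")) {
    three_prime <- "cyclic_phosphate"; s <- substring(s, 1, nchar(s) - 2)
  } else if (endsWith(s, "p")) {
    three_prime <- "phosphate"; s <- substring(s, 1, nchar(s) - 1)
  }
  residues <- character(); codes <- character(); placements <- character()
  i <- 1L; nc <- nchar(s)
  while (i <= nc) {
    ch <- substring(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substring(s, i), fixed = TRUE)
      if (j < 0) stop("unclosed '[' in sequence: ", x)
      tok <- substring(s, i + 1L, i + j - 2L)
      pl <- NA_character_
      if (grepl("/[bs]$", tok)) {
        pl <- if (endsWith(tok, "/s")) "sugar" else "base"
        tok <- substring(tok, 1, nchar(tok) - 2L)
      }
      row <- modification_registry(tok)
      if (is.na(pl)) {
        pls <- mod_resolved_placements(tok)
        pl <- pls[1]
      }
      targets <- strsplit(row$targets, ",", fixed = TRUE)[[1]]
      residues <- c(residues, targets[1])
      codes <- c(codes, tok); placements <- c(placements, pl)
      i <- i + j
    } else if (ch %in% c("A", "C", "G", "U")) {
      residues <- c(residues, ch)
      codes <- c(codes, NA_character_); placements <- c(placements, NA_character_)
      i <- i + 1L
    } else if (ch == "T") {
      residues <- c(residues, "U")
      codes <- c(codes, NA_character_); placements <- c(placements, NA_character_)
      i <- i + 1L
    } else {
      stop("illegal character '", ch, "' in sequence: ", x)
    }
  }
  na_sequence(residues, codes, placements, five_prime, three_prime)
}

#' Format an `na_sequence` in bracket notation
#' @param x An `na_sequence`. @param ... Unused.
#' @return A string; inverse of [parse_sequence()].
#' @export
format.na_sequence <- function(x, ...) {
  toks <- x$residues
  for (i in which(!is.na(x$mod_code))) {
    row <- modification_registry(x$mod_code[i])
    suffix <- ""
    if (row$placement == "either") {
      suffix <- if (x$mod_placement[i] == "sugar") "/s" else "/b"
    }
    toks[i] <- paste0("[", x$mod_code[i], suffix, "]")
  }
  paste0(if (x$five_prime == "phosphate") "p" else "",
         paste(toks, collapse = ""),
         switch(x$three_prime, OH = "", phosphate = "p", cyclic_phosphate = ">p"))
}

#' @export
print.na_sequence <- function(x, ...) {
  cat("<na_sequence> ", format(x), "  (", length(x$residues), " nt, ",
      sprintf("%.5f", sequence_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' @export
length.na_sequence <- function(x) length(x$residues)

#' Elemental formula of an oligonucleotide
#'
#' The neutral molecule: nucleosides joined by phosphodiester bonds
#' (each internal linkage adds HPO3 and removes H2O), plus modification
#' shifts and terminal groups (5'-phosphate +HPO3; 3'-phosphate +HPO3;
#' 2',3'-cyclic phosphate +HPO3 -H2O).
#'
#' @param seq An `na_sequence`.
#' @return A `chem_formula`.
#' @export
sequence_formula <- function(seq) {
  stopifnot(inherits(seq, "na_sequence"))
  n <- length(seq$residues)
  counts <- stats::setNames(rep(0, length(.ELEMENT_MASSES)), names(.ELEMENT_MASSES))
  add <- function(counts, f, k = 1) {
    f <- chem_formula(f)
    counts[names(f)] <- counts[names(f)] + k * as.numeric(f)
    counts
  }
  for (b in c("A", "C", "G", "U")) {
    k <- sum(seq$residues == b)
    if (k > 0) counts <- add(counts, .NUCLEOSIDE_FORMULAS[[b]], k)
  }
  for (i in which(!is.na(seq$mod_code))) {
    counts <- add(counts, modification_registry(seq$mod_code[i])$formula)
  }
  counts <- add(counts, "H2O", -(n - 1))
  counts <- add(counts, "HPO3", n - 1)
  if (seq$five_prime == "phosphate") counts <- add(counts, "HPO3")
  if (seq$three_prime == "phosphate") counts <- add(counts, "HPO3")
  if (seq$three_prime == "cyclic_phosphate") {
    counts <- add(counts, "HPO3"); counts <- add(counts, "H2O", -1)
  }
  chem_formula(counts)
}

.nucleoside_masses <- c(
  A = 267.09675391931, C = 243.08552052931, G = 283.09166853891, U = 244.06953611204
)
.base_masses <- c(
  A = 135.05449518435, C = 111.04326179435, G = 151.04940980395, U = 112.02727737708
)

## mass-shift lookup keyed by modification code (rebuilt on registry load)
mod_mass_shift <- function(code) {
  tab <- modification_registry()
  stats::setNames(tab$mass_shift, tab$code)[code]
}

#' Neutral monoisotopic mass of an oligonucleotide
#' @param seq An `na_sequence`.
#' @return Mass in Da; equals `formula_mass(sequence_formula(seq))`.
#' @export
sequence_mass <- function(seq) {
  stopifnot(inherits(seq, "na_sequence"))
  n <- length(seq$residues)
  m <- sum(.nucleoside_masses[seq$residues]) +
    (n - 1) * (mass_constants[["hpo3"]] - mass_constants[["water"]])
  mods <- seq$mod_code[!is.na(seq$mod_code)]
  if (length(mods)) m <- m + sum(mod_mass_shift(mods))
  if (seq$five_prime == "phosphate") m <- m + mass_constants[["hpo3"]]
  m + switch(seq$three_prime, OH = 0,
             phosphate = mass_constants[["hpo3"]],
             cyclic_phosphate = mass_constants[["hpo3"]] - mass_constants[["water"]])
}

## Extract a contiguous subsequence [from, to] as a free oligonucleotide
## with the given terminus chemistry (modifications carried along).
subsequence <- function(seq, from, to, five_prime, three_prime) {
  idx <- from:to
  na_sequence(seq$residues[idx], seq$mod_code[idx], seq$mod_placement[idx],
              five_prime, three_prime)
}
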