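## Canonical ribonucleotide building blocks. Masses derive from the neutral
## nucleoside composition; the internal residue (within a phosphodiester
## chain) is nucleoside + HPO3 - H2O.

.NUCLEOSIDE_FORMULAS <- list(
  A = "C10H13N5O4",
  C = "C9H13N3O5",
  G = "C10H13N5O5",
  U = "C9H12N2O6"
)

## Neutral nucleobase (BH) released in a-B fragmentation.
.BASE_FORMULAS <- list(
  A = "C5H5N5",
  C = "C4H5N3O",
  G = "C5H5N5O",
  U = "C4H4N2O2"
)

#' Canonical ribonucleotide table
#'
#' @return A data frame with one row per canonical ribonucleotide (A, C, G,
#'   U): the nucleoside formula, the neutral base (BH) formula, the internal
#'   residue formula and their monoisotopic masses.
#' @export
ribonucleotides <- function() {
  codes <- names(.NUCLEOSIDE_FORMULAS)
  data.frame(
    code = codes,
    nucleoside_formula = unlist(.NUCLEOSIDE_FORMULAS),
    base_formula = unlist(.BASE_FORMULAS),
    residue_formula = vapply(codes, function(b)
      format_formula(chem_formula(.NUCLEOSIDE_FORMULAS[[b]]) +
                     chem_formula("HPO3") - chem_formula("H2O")), ""),
    nucleoside_mass = vapply(codes, function(b)
      formula_mass(.NUCLEOSIDE_FORMULAS[[b]]), 0),
    base_mass = vapply(codes, function(b) formula_mass(.BASE_FORMULAS[[b]]), 0),
    row.names = NULL
  )
}

.registry_env <- new.env(parent = emptyenv())

#' Load a modification registry
#'
#' The registry is a tab-separated table with columns `code` (short search
#' code; a trailing `?` marks modifications whose placement on the base or
#' the ribose is ambiguous and must be searched both ways), `name`,
#' `formula` (elemental mass-shift formula relative to the unmodified
#' residue), `placement` (`base`, `sugar`, `either` or `split`), `targets`
#' (comma-separated canonical bases the modification can sit on),
#' `sugar_part` (for `split`/`either` entries: the portion of the shift
#' located on the ribose, e.g. a 2'-O-methyl) and `isobaric`
#' (comma-separated names of the isobaric modifications the code
#' represents).
#'
#' A curated registry covering common tRNA/rRNA modifications ships with the
#' package and is loaded automatically; call this function with your own
#' file to extend or replace it.
#'
#' @param path Path to a registry TSV; `NULL` reloads the built-in table.
#' @return (Invisibly) the registry data frame.
#' @export
load_modification_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "modifications.tsv", package = "oligosearch")
    if (path == "") { # not installed yet (e.g. pkgload); fall back to source tree
      path <- file.path("inst", "extdata", "modifications.tsv")
    }
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  needed <- c("code", "name", "formula", "placement", "targets", "sugar_part", "isobaric")
  if (!all(needed %in% names(tab))) {
    stop("modification registry must have columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(tab$code)) stop("duplicate modification codes in registry")
  bad <- !tab$placement %in% c("base", "sugar", "either", "split")
  if (any(bad)) stop("invalid placement value(s): ", paste(unique(tab$placement[bad]), collapse = ", "))
  # sanity checks mirroring the registry invariants
  for (i in seq_len(nrow(tab))) {
    m <- formula_mass(tab$formula[i])
    if (m <= -200 || m >= 500) {
      stop("mass shift of '", tab$code[i], "' outside sanity bounds (-200, 500) Da")
    }
    ambiguous <- grepl("\\?$", tab$code[i])
    if (ambiguous != (tab$placement[i] == "either")) {
      stop("code '", tab$code[i], "': trailing '?' must correspond to placement 'either'")
    }
    if (tab$placement[i] == "split" && !nzchar(tab$sugar_part[i])) {
      stop("code '", tab$code[i], "': placement 'split' requires a sugar_part formula")
    }
  }
  tab$mass_shift <- vapply(tab$formula, formula_mass, 0, USE.NAMES = FALSE)
  assign("modifications", tab, envir = .registry_env)
  invisible(tab)
}

#' Modification registry accessor
#'
#' @param code Optional search code; when given, the single matching registry
#'   row is returned (error if absent).
#' @return The registry data frame, or one row of it.
#' @export
modification_registry <- function(code = NULL) {
  if (!exists("modifications", envir = .registry_env)) load_modification_registry()
  tab <- get("modifications", envir = .registry_env)
  if (is.null(code)) return(tab)
  i <- match(code, tab$code)
  if (is.na(i)) stop("unknown modification code: '", code, "'")
  tab[i, , drop = FALSE]
}

## Portion of a modification's mass shift that sits on the nucleobase (and is
## therefore lost in an a-B ion), given the resolved placement.
mod_base_shift_formula <- function(code, placement) {
  row <- modification_registry(code)
  full <- chem_formula(row$formula)
  sugar_part <- if (nzchar(row$sugar_part)) chem_formula(row$sugar_part) else NULL
  switch(placement,
    base = full,
    sugar = if (is.null(sugar_part)) chem_formula() else full - sugar_part,
    split = full - sugar_part,
    stop("unresolved placement '", placement, "' for modification '", code, "'")
  )
}

## Resolved placements to enumerate for a registry code.
mod_resolved_placements <- function(code) {
  row <- modification_registry(code)
  switch(row$placement,
    either = c("base", "sugar"),
    row$placement
  )
}

.onLoad <- function(libname, pkgname) {
  load_modification_registry()
}
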