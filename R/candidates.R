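#' Build a searchable candidate database
#'
#' Parses target (and decoy) FASTA records, digests them in silico,
#' enumerates variable-modification placements and collapses duplicates:
#' oligonucleotides mapping to multiple database entries are kept once per
#' distinct (modified sequence, termini), with all parent locations
#' recorded. Candidates are sorted by neutral mass so that precursor lookup
#' is a binary-search range query.
#'
#' @param records FASTA records (data frame with `id`, `sequence`), targets
#'   plus any `DECOY_`-prefixed decoys.
#' @param config A [search_config()].
#' @return A `candidate_db`: list with `table` (data frame: `key`, `mass`,
#'   `length`, `n_mods`, `missed_cleavages`, `is_decoy`, `locations`) and
#'   `sequences` (list of `na_sequence`, parallel to `table`).
#' @export
build_candidate_db <- function(records, config) {
  key_env <- new.env(parent = emptyenv())
  seqs <- list(); keys <- character(); mass <- numeric(); len <- integer()
  nmods <- integer(); mc <- integer(); decoy <- logical(); locs <- list()
  for (r in seq_len(nrow(records))) {
    parent <- parse_sequence(records$sequence[r])
    is_dec <- startsWith(records$id[r], "DECOY_")
    products <- switch(config$digestion,
      rnase_t1 = digest_rnase_t1(parent, config$missed_cleavages,
                                 min_length = config$min_length,
                                 max_length = config$max_length,
                                 cleave_modified_g = config$cleave_modified_g,
                                 parent_id = records$id[r]),
      unspecific = digest_unspecific(parent, config$min_length,
                                     config$max_length,
                                     parent_id = records$id[r]),
      none = list(list(parent_id = records$id[r], start = 1L,
                       end = length(parent$residues), missed_cleavages = 0L,
                       sequence = parent)),
      stop("unknown digestion mode: ", config$digestion)
    )
    for (p in products) {
      cands <- enumerate_modifications(p, config$variable_mods,
                                       config$fixed_mods, config$max_mods)
      for (cand in cands) {
        key <- format(cand$sequence)
        loc <- sprintf("%s:%d-%d", cand$parent_id, cand$start, cand$end)
        idx <- key_env[[key]]
        if (is.null(idx)) {
          i <- length(seqs) + 1L
          key_env[[key]] <- i
          seqs[[i]] <- cand$sequence
          keys[i] <- key; mass[i] <- cand$neutral_mass
          len[i] <- length(cand$sequence$residues)
          nmods[i] <- cand$n_mods; mc[i] <- cand$missed_cleavages
          decoy[i] <- is_dec; locs[[i]] <- loc
        } else {
          locs[[idx]] <- union(locs[[idx]], loc)
          # a sequence present among targets and decoys counts as target
          decoy[idx] <- decoy[idx] && is_dec
        }
      }
    }
  }
  if (!length(seqs)) stop("candidate database is empty")
  ord <- order(mass)
  db <- list(
    table = data.frame(key = keys[ord], mass = mass[ord], length = len[ord],
                       n_mods = nmods[ord], missed_cleavages = mc[ord],
                       is_decoy = decoy[ord], stringsAsFactors = FALSE),
    sequences = seqs[ord]
  )
  db$table$locations <- I(locs[ord])
  class(db) <- "candidate_db"
  db
}

#' @export
print.candidate_db <- function(x, ...) {
  cat("<candidate_db> ", nrow(x$table), " candidates (",
      sum(x$table$is_decoy), " decoy), mass range ",
      sprintf("%.2f-%.2f", min(x$table$mass), max(x$table$mass)), " Da\n",
      sep = "")
  invisible(x)
}

#' Range query on the mass-sorted candidate table
#'
#' Returns the indices of all candidates whose neutral mass lies within
#' `tol_ppm` of `mass`. Equivalent to a brute-force scan, but O(log n).
#'
#' @param db A `candidate_db`. @param mass Query neutral mass in Da.
#' @param tol_ppm Relative tolerance in ppm (applied to candidate mass).
#' @return Integer vector of row indices into `db$table`.
#' @export
query_mass_index <- function(db, mass, tol_ppm) {
  masses <- db$table$mass
  # |mass - m| <= m * tol  =>  m in [mass/(1+tol), mass/(1-tol)]
  tol <- tol_ppm * 1e-6
  lo <- mass / (1 + tol); hi <- mass / (1 - tol)
  i <- findInterval(lo, masses, left.open = TRUE) + 1L
  j <- findInterval(hi, masses)
  if (i > j) integer() else i:j
}
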