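#' Target/decoy q-values for oligonucleotide-spectrum matches
#'
#' Only rank-1 OSMs are used. For a score threshold s, FDR(s) = #decoys at
#' or above s / max(1, #targets at or above s); the q-value of a match is
#' the minimum FDR over all thresholds at or below its score (monotonized),
#' capped at 1. Decoy matches are annotated too but should be excluded from
#' reported lists (see [filter_fdr()]).
#'
#' @param osms OSM data frame from [search_run()] (needs `hyperscore`,
#'   `is_decoy`, `rank`).
#' @return The rank-1 subset with a `q_value` column appended.
#' @export
compute_qvalues <- function(osms) {
  osms <- osms[osms$rank == 1L, , drop = FALSE]
  if (!nrow(osms)) stop("no rank-1 matches to validate")
  if (!any(osms$is_decoy)) {
    stop("no decoy matches present; search against a target/decoy database ",
         "(see generate_decoys) to estimate q-values")
  }
  ord <- order(-osms$hyperscore)
  dec <- osms$is_decoy[ord]
  fdr <- cumsum(dec) / pmax(1, cumsum(!dec))
  q <- rev(cummin(rev(pmin(fdr, 1))))
  osms$q_value <- NA_real_
  osms$q_value[ord] <- q
  osms
}

#' Filter matches to an FDR threshold
#'
#' @param osms Output of [compute_qvalues()].
#' @param threshold q-value cutoff (e.g. 0.01).
#' @param keep_decoys Keep decoy matches in the output? Default drops them.
#' @return Target OSMs with `q_value <= threshold`, ordered by decreasing
#'   score.
#' @export
filter_fdr <- function(osms, threshold, keep_decoys = FALSE) {
  out <- osms[osms$q_value <= threshold & (keep_decoys | !osms$is_decoy), ,
              drop = FALSE]
  out[order(-out$hyperscore), , drop = FALSE]
}

#' Remove single-hit identifications
#'
#' Drops oligonucleotide sequences (including modification state) supported
#' by only one spectrum within each run.
#'
#' @param osms OSM data frame (typically FDR-filtered targets).
#' @param per_run Count spectra per `run_id` (default) or over the whole
#'   table.
#' @return The OSMs whose sequence has spectral count >= 2.
#' @export
remove_single_hits <- function(osms, per_run = TRUE) {
  if (!nrow(osms)) return(osms)
  grp <- if (per_run && "run_id" %in% names(osms)) {
    paste(osms$run_id, osms$sequence, sep = "\r")
  } else osms$sequence
  counts <- table(grp)
  osms[counts[grp] >= 2L, , drop = FALSE]
}

#' Per-parent sequence coverage and spectral counts
#'
#' Credits every matching location of each identified oligonucleotide
#' (set `unique_only = TRUE` to count only unambiguously mapping ones) and
#' reports the union of covered positions over the parent length.
#'
#' @param osms OSM data frame (use FDR-filtered targets).
#' @param parents FASTA records data frame (`id`, `sequence`).
#' @param unique_only Only credit oligonucleotides with a single location.
#' @return A list of coverage reports, one per parent: `parent_id`,
#'   `length`, `covered` (integer positions), `coverage_fraction`, and
#'   `oligos` (data frame of per-oligo spectral counts and coordinates).
#' @export
sequence_coverage <- function(osms, parents, unique_only = FALSE) {
  reports <- list()
  for (i in seq_len(nrow(parents))) {
    pid <- parents$id[i]
    plen <- length(parse_sequence(parents$sequence[i])$residues)
    covered <- integer()
    oligo_rows <- list()
    if (nrow(osms)) {
      counts <- table(osms$sequence)
      loc_of <- tapply(osms$locations, osms$sequence, `[`, 1)
      for (sq in names(counts)) {
        locs <- strsplit(loc_of[[sq]], ";", fixed = TRUE)[[1]]
        if (unique_only && length(locs) > 1) next
        here <- grep(paste0("^", pid, ":"), locs, value = TRUE)
        for (l in here) {
          se <- as.integer(strsplit(sub("^.*:", "", l), "-", fixed = TRUE)[[1]])
          covered <- union(covered, se[1]:se[2])
          oligo_rows[[length(oligo_rows) + 1L]] <- data.frame(
            sequence = sq, start = se[1], end = se[2],
            spectral_count = as.integer(counts[[sq]]), stringsAsFactors = FALSE)
        }
      }
    }
    reports[[pid]] <- list(
      parent_id = pid, length = plen, covered = sort(covered),
      coverage_fraction = length(covered) / plen,
      oligos = if (length(oligo_rows)) do.call(rbind, oligo_rows)
               else data.frame(sequence = character(), start = integer(),
                               end = integer(), spectral_count = integer())
    )
  }
  reports
}

#' Spectral counts per modification code
#'
#' Counts how many OSMs contain each modification search code; an OSM
#' carrying two distinct codes increments both rows (an OSM with the same
#' code twice increments it once).
#'
#' @param osms OSM data frame.
#' @return Data frame with `search_code` and `spectral_count`, sorted by
#'   decreasing count.
#' @export
aggregate_modification_report <- function(osms) {
  if (!nrow(osms)) {
    return(data.frame(search_code = character(), spectral_count = integer()))
  }
  codes_per <- lapply(osms$sequence, function(s) {
    m <- regmatches(s, gregexpr("\\[([^]]+)\\]", s))[[1]]
    unique(sub("/[bs]$", "", gsub("\\[|\\]", "", m)))
  })
  tab <- table(unlist(codes_per))
  if (!length(tab)) {
    return(data.frame(search_code = character(), spectral_count = integer()))
  }
  out <- data.frame(search_code = names(tab),
                    spectral_count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$spectral_count), , drop = FALSE]
}

#' Majority-replicate filter and effective FDR
#'
#' Keeps sequences identified in more than half of the replicates (pooled
#' OSMs with a `run_id` column), then recomputes the decoy/target ratio
#' among the surviving matches ("effective FDR").
#'
#' @param osms OSMs from several runs, with q-values, including decoys
#'   (use `filter_fdr(..., keep_decoys = TRUE)`).
#' @param n_replicates Total number of replicates; default: number of
#'   distinct `run_id` values.
#' @return List with `osms` (survivors) and `effective_fdr`.
#' @export
filter_majority_replicates <- function(osms, n_replicates = NULL) {
  if (is.null(n_replicates)) n_replicates <- length(unique(osms$run_id))
  reps <- tapply(osms$run_id, osms$sequence, function(x) length(unique(x)))
  keep <- names(reps)[reps > n_replicates / 2]
  out <- osms[osms$sequence %in% keep, , drop = FALSE]
  eff <- sum(out$is_decoy) / max(1, sum(!out$is_decoy))
  list(osms = out[!out$is_decoy, , drop = FALSE], effective_fdr = eff)
}
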