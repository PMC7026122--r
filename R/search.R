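#' Search parameter configuration
#'
#' Mirrors the parameter set of a typical oligonucleotide database search:
#' ion types, ppm tolerances, salt adducts, variable/fixed modifications
#' with a per-oligonucleotide cap, isotopologue precursor offsets, digestion
#' settings and decoy/ranking behaviour.
#'
#' @param precursor_tol_ppm,fragment_tol_ppm Match tolerances in ppm
#'   (default 3, suitable for Orbitrap-class data).
#' @param ion_types Fragment ion series to match (default all nine).
#' @param adducts Character vector of cation compositions searched as salt
#'   adducts, e.g. `c("Na", "K", "NaK")`; each cation carries +1.
#' @param isotope_offsets Integer range of isotopologue offsets k; the
#'   precursor mass is corrected by `-k` neutron masses. A `-1` entry
#'   recovers precursors whose selected-ion m/z was estimated below the
#'   monoisotopic peak.
#' @param variable_mods,fixed_mods Modification registry codes.
#' @param max_mods Maximum variable modifications per oligonucleotide.
#' @param digestion `"rnase_t1"`, `"unspecific"` or `"none"`.
#' @param missed_cleavages Maximum missed cleavages (RNase digestion).
#' @param min_length,max_length Candidate length bounds in nt.
#' @param cleave_modified_g Treat modified G as cleavable by RNase T1?
#' @param precursor_charges Charges tried when a spectrum's precursor
#'   charge is unknown (0).
#' @param max_fragment_charge Cap on fragment charge magnitude; fragments
#'   are generated from -1 down to `max(precursor_charge + 1,
#'   -max_fragment_charge)`.
#' @param top_hits Matches reported per spectrum (default 1).
#' @param intensity_mode `"raw"` (hyperscore uses intensities as stored) or
#'   `"base_peak"` (normalized to base peak = 1 before scoring).
#' @return A `search_config` list.
#' @export
search_config <- function(precursor_tol_ppm = 3, fragment_tol_ppm = 3,
                          ion_types = ION_TYPES, adducts = character(),
                          isotope_offsets = 0L,
                          variable_mods = character(), fixed_mods = character(),
                          max_mods = 2L, digestion = "rnase_t1",
                          missed_cleavages = 1L, min_length = 3L,
                          max_length = 40L, cleave_modified_g = TRUE,
                          precursor_charges = -2:-7,
                          max_fragment_charge = 4L, top_hits = 1L,
                          intensity_mode = "raw") {
  stopifnot(precursor_tol_ppm > 0, fragment_tol_ppm > 0,
            all(diff(isotope_offsets) >= 0), max_mods >= 0,
            all(precursor_charges < 0), max_fragment_charge >= 1,
            top_hits >= 1)
  ion_types <- match.arg(ion_types, ION_TYPES, several.ok = TRUE)
  digestion <- match.arg(digestion, c("rnase_t1", "unspecific", "none"))
  intensity_mode <- match.arg(intensity_mode, c("raw", "base_peak"))
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_ppm = fragment_tol_ppm, ion_types = ion_types,
                 adducts = adducts, isotope_offsets = as.integer(isotope_offsets),
                 variable_mods = variable_mods, fixed_mods = fixed_mods,
                 max_mods = as.integer(max_mods), digestion = digestion,
                 missed_cleavages = as.integer(missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = if (is.finite(max_length)) as.integer(max_length) else max_length,
                 cleave_modified_g = cleave_modified_g,
                 precursor_charges = as.integer(precursor_charges),
                 max_fragment_charge = as.integer(max_fragment_charge),
                 top_hits = as.integer(top_hits),
                 intensity_mode = intensity_mode),
            class = "search_config")
}

## fragment charges scored against a precursor of charge z
fragment_charges_for <- function(precursor_charge, max_fragment_charge) {
  lo <- max(precursor_charge + 1L, -max_fragment_charge)
  if (lo > -1L) lo <- -1L
  -1L:lo
}

#' Map a spectrum's precursor onto candidate oligonucleotides
#'
#' The experimental neutral mass is M_exp = |z| * mz + |z| * m_proton. For
#' every configured adduct (including none) and isotopologue offset k, the
#' corrected mass M_exp - k * m_neutron - shift(adduct) is compared against
#' the candidate index at the precursor tolerance; every matching
#' combination is returned.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param db A `candidate_db`.
#' @param config A [search_config()].
#' @return Data frame with `cand`, `charge`, `adduct` (`""` = none), `k`,
#'   `ppm_error`; zero rows if nothing matches.
#' @export
find_candidates <- function(spectrum, db, config) {
  charges <- if (spectrum$precursor_charge != 0L) spectrum$precursor_charge
             else config$precursor_charges
  adducts <- c("", config$adducts)
  shifts <- c(0, vapply(config$adducts, adduct_mass_shift, 0))
  out <- list()
  for (z in charges) {
    m_exp <- mass_from_mz(spectrum$precursor_mz, z)
    for (ai in seq_along(adducts)) {
      for (k in config$isotope_offsets) {
        m_test <- m_exp - k * mass_constants[["neutron"]] - shifts[ai]
        idx <- query_mass_index(db, m_test, config$precursor_tol_ppm)
        if (length(idx)) {
          out[[length(out) + 1L]] <- data.frame(
            cand = idx, charge = z, adduct = adducts[ai], k = k,
            ppm_error = ppm_error(m_test, db$table$mass[idx]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(cand = integer(), charge = integer(),
                      adduct = character(), k = integer(),
                      ppm_error = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Match experimental peaks to theoretical fragments
#'
#' Each experimental peak pairs with at most one fragment: the nearest
#' within the ppm tolerance (ties broken toward the lower-m/z fragment),
#' and each fragment is matched by at most one peak (the closest).
#'
#' @param spectrum An `ms2_spectrum`.
#' @param fragments Theoretical fragments as from
#'   [generate_theoretical_spectrum()] (sorted by m/z).
#' @param fragment_tol_ppm Tolerance in ppm (relative to fragment m/z).
#' @return Data frame with `peak` (index into spectrum peaks), `fragment`
#'   (row index into `fragments`), `mz`, `intensity`, `ion_type`.
#' @export
match_peaks <- function(spectrum, fragments, fragment_tol_ppm = 3) {
  fmz <- fragments$mz
  pmz <- spectrum$mz
  empty <- data.frame(peak = integer(), fragment = integer(), mz = numeric(),
                      intensity = numeric(), ion_type = character(),
                      stringsAsFactors = FALSE)
  if (!length(fmz) || !length(pmz)) return(empty)
  pos <- findInterval(pmz, fmz)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(fmz))
  d_lo <- abs(pmz - fmz[lo]); d_hi <- abs(pmz - fmz[hi])
  # ties (equal distance) go to the lower-m/z fragment, i.e. `lo`
  pick <- ifelse(d_hi < d_lo, hi, lo)
  dist <- pmin(d_lo, d_hi)
  within <- dist <= fmz[pick] * fragment_tol_ppm * 1e-6
  peak_idx <- which(within); frag_idx <- pick[within]
  if (!length(peak_idx)) return(empty)
  # enforce one peak per fragment: keep the closest
  d <- dist[within]
  ord <- order(frag_idx, d)
  keep <- !duplicated(frag_idx[ord])
  sel <- ord[keep]
  data.frame(peak = peak_idx[sel], fragment = frag_idx[sel],
             mz = pmz[peak_idx[sel]], intensity = spectrum$intensity[peak_idx[sel]],
             ion_type = fragments$ion_type[frag_idx[sel]],
             stringsAsFactors = FALSE)
}

#' Hyperscore of a set of matched peaks
#'
#' score = ln(1 + sum of matched intensities) + ln(Nf!) + ln(Nr!), where Nf
#' and Nr count matched 5'-series (a-B/a/b/c/d) and 3'-series (w/x/y/z)
#' ions; factorials are computed via the log-gamma function. An empty match
#' set scores 0.
#'
#' @param matches Data frame from [match_peaks()] (columns `intensity`,
#'   `ion_type`).
#' @return Non-negative score.
#' @export
hyperscore <- function(matches) {
  if (!nrow(matches)) return(0.0)
  n_f <- sum(matches$ion_type %in% FIVE_PRIME_IONS)
  n_r <- sum(matches$ion_type %in% THREE_PRIME_IONS)
  log1p(sum(matches$intensity)) + lgamma(n_f + 1) + lgamma(n_r + 1)
}

## residue string (mods stripped) + termini, for placement-isomer detection
plain_key <- function(seq) {
  paste0(paste(seq$residues, collapse = ""), "|", seq$five_prime, "|",
         seq$three_prime, "|",
         paste(sort(seq$mod_code[!is.na(seq$mod_code)]), collapse = ","))
}

#' Search a set of MS2 spectra against a candidate database
#'
#' For every spectrum, candidates are located by corrected precursor mass
#' ([find_candidates()]), scored by [hyperscore()] against their theoretical
#' spectra, and ranked (ties: fewer modifications first, then lexicographic
#' sequence). When the reported match ties in score with a placement isomer
#' (same residues and modification multiset, different localization) it is
#' flagged `localization_ambiguous`. Results are independent across spectra
#' and deterministic for fixed inputs.
#'
#' @param spectra List of `ms2_spectrum` (or an `ms_run`, whose `$ms2` is
#'   used).
#' @param db A `candidate_db` from [build_candidate_db()].
#' @param config A [search_config()].
#' @param run_id Optional run/replicate label stored on each match.
#' @return A data frame of oligonucleotide-spectrum matches (OSMs), one row
#'   per (spectrum, rank): columns `spectrum_id`, `rt`, `precursor_mz`,
#'   `charge`, `sequence`, `mass`, `length`, `n_mods`, `is_decoy`,
#'   `hyperscore`, `n_matched`, `n_forward`, `n_reverse`, `adduct`, `k`,
#'   `precursor_error_ppm`, `rank`, `localization_ambiguous`, `locations`,
#'   `run_id`. Counts of searched/matched/skipped spectra are attached as
#'   attribute `"log"`.
#' @export
search_run <- function(spectra, db, config, run_id = "run1") {
  if (inherits(spectra, "ms_run")) spectra <- spectra$ms2
  if (!nrow(db$table)) stop("candidate database is empty")
  theo_cache <- new.env(parent = emptyenv())
  n_searched <- 0L; n_matched <- 0L; n_skipped <- 0L
  rows <- vector("list", length(spectra))
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    if (is.na(sp$precursor_mz)) { n_skipped <- n_skipped + 1L; next }
    n_searched <- n_searched + 1L
    hits <- find_candidates(sp, db, config)
    if (!nrow(hits)) next
    if (config$intensity_mode == "base_peak" && length(sp$intensity)) {
      sp$intensity <- sp$intensity / max(sp$intensity)
    }
    # per (candidate, charge): score once; keep the annotation (adduct, k)
    # with the smallest absolute precursor error
    hits <- hits[order(hits$cand, hits$charge, abs(hits$ppm_error)), , drop = FALSE]
    uniq <- !duplicated(hits[, c("cand", "charge")])
    hits <- hits[uniq, , drop = FALSE]
    scores <- numeric(nrow(hits)); nm <- integer(nrow(hits))
    nf <- integer(nrow(hits)); nr <- integer(nrow(hits))
    for (h in seq_len(nrow(hits))) {
      cand <- hits$cand[h]
      zr <- fragment_charges_for(hits$charge[h], config$max_fragment_charge)
      key <- paste0(cand, "@", length(zr))
      frag <- theo_cache[[key]]
      if (is.null(frag)) {
        frag <- generate_theoretical_spectrum(db$sequences[[cand]],
                                              config$ion_types, zr)
        theo_cache[[key]] <- frag
      }
      m <- match_peaks(sp, frag, config$fragment_tol_ppm)
      scores[h] <- hyperscore(m)
      nm[h] <- nrow(m)
      nf[h] <- sum(m$ion_type %in% FIVE_PRIME_IONS)
      nr[h] <- sum(m$ion_type %in% THREE_PRIME_IONS)
    }
    keys <- db$table$key[hits$cand]
    ord <- order(-scores, db$table$n_mods[hits$cand], keys)
    hits <- hits[ord, , drop = FALSE]
    scores <- scores[ord]; nm <- nm[ord]; nf <- nf[ord]; nr <- nr[ord]
    take <- seq_len(min(config$top_hits, nrow(hits)))
    # placement-isomer ambiguity among equal-scoring candidates
    pk <- vapply(hits$cand, function(ci) plain_key(db$sequences[[ci]]), "")
    amb <- vapply(take, function(r) {
      tied <- which(abs(scores - scores[r]) < 1e-9 & seq_along(scores) != r)
      any(pk[tied] == pk[r])
    }, TRUE)
    sel <- hits[take, , drop = FALSE]
    rows[[si]] <- data.frame(
      spectrum_id = sp$native_id, rt = sp$rt, precursor_mz = sp$precursor_mz,
      charge = sel$charge, sequence = db$table$key[sel$cand],
      mass = db$table$mass[sel$cand], length = db$table$length[sel$cand],
      n_mods = db$table$n_mods[sel$cand], is_decoy = db$table$is_decoy[sel$cand],
      hyperscore = scores[take], n_matched = nm[take], n_forward = nf[take],
      n_reverse = nr[take], adduct = sel$adduct, k = sel$k,
      precursor_error_ppm = sel$ppm_error, rank = take,
      localization_ambiguous = amb,
      locations = vapply(db$table$locations[sel$cand], paste, "", collapse = ";"),
      run_id = run_id, stringsAsFactors = FALSE)
    n_matched <- n_matched + 1L
  }
  osms <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(osms)) {
    osms <- data.frame()
  }
  attr(osms, "log") <- c(searched = n_searched, matched = n_matched,
                         skipped = n_skipped)
  osms
}
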