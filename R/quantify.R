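#' Export label-free quantification targets
#'
#' From high-confidence identifications (e.g. FDR-filtered to 1%), builds
#' the target coordinates a targeted feature detector needs: one row per
#' distinct (oligonucleotide, charge, adduct) observed, with the chemical
#' sum formula, the median retention time over its OSMs, and the expected
#' m/z.
#'
#' @param osms Target OSM data frame (after [filter_fdr()]).
#' @return Data frame with `sequence`, `sum_formula`, `charge`, `adduct`,
#'   `median_rt`, `mz`, `n_osms`.
#' @export
export_quant_targets <- function(osms) {
  cols <- c("sequence", "sum_formula", "charge", "adduct", "median_rt",
            "mz", "n_osms")
  if (!nrow(osms)) {
    out <- data.frame(sequence = character(), sum_formula = character(),
                      charge = integer(), adduct = character(),
                      median_rt = numeric(), mz = numeric(),
                      n_osms = integer(), stringsAsFactors = FALSE)
    return(out[, cols])
  }
  grp <- interaction(osms$sequence, osms$charge, osms$adduct, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(osms)), grp), function(idx) {
    o <- osms[idx, , drop = FALSE]
    seq <- parse_sequence(o$sequence[1])
    mass <- sequence_mass(seq)
    shift <- if (nzchar(o$adduct[1])) adduct_mass_shift(o$adduct[1]) else 0
    data.frame(sequence = o$sequence[1],
               sum_formula = format_formula(sequence_formula(seq)),
               charge = o$charge[1], adduct = o$adduct[1],
               median_rt = stats::median(o$rt),
               mz = mz_from_mass(mass + shift, o$charge[1]),
               n_osms = nrow(o), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sequence, out$charge, out$adduct), cols, drop = FALSE]
}

#' Targeted XIC quantification on an MS1 map
#'
#' A deliberately simple stand-in for full chromatographic feature
#' detection: for each target, sums the MS1 peak intensities within the ppm
#' tolerance of the monoisotopic and first two isotopologue m/z values,
#' over retention times within `rt_window_s` of the target's median RT.
#'
#' @param ms1 List of MS1 scans (as in `ms_run$ms1`) or an `ms_run`.
#' @param targets Data frame from [export_quant_targets()].
#' @param mz_tol_ppm m/z tolerance (default 10 ppm).
#' @param rt_window_s Half-width of the RT integration window in seconds.
#' @param replicate_id Label stored on the output rows.
#' @return `targets` with `intensity`, `rt_lo`, `rt_hi`, `replicate_id`
#'   columns appended (intensity 0 when no signal).
#' @export
xic_quantify <- function(ms1, targets, mz_tol_ppm = 10, rt_window_s = 60,
                         replicate_id = "rep1") {
  if (inherits(ms1, "ms_run")) ms1 <- ms1$ms1
  rts <- vapply(ms1, function(s) s$rt, 0)
  spacing <- mass_constants[["c13_spacing"]]
  out <- targets
  out$intensity <- 0
  out$rt_lo <- targets$median_rt - rt_window_s
  out$rt_hi <- targets$median_rt + rt_window_s
  out$replicate_id <- replicate_id
  for (i in seq_len(nrow(targets))) {
    iso_mz <- targets$mz[i] + (0:2) * spacing / abs(targets$charge[i])
    scans <- which(rts >= out$rt_lo[i] & rts <= out$rt_hi[i])
    total <- 0
    for (s in scans) {
      mz <- ms1[[s]]$mz
      for (m in iso_mz) {
        tol <- m * mz_tol_ppm * 1e-6
        hit <- mz >= m - tol & mz <= m + tol
        if (any(hit)) total <- total + sum(ms1[[s]]$intensity[hit])
      }
    }
    out$intensity[i] <- total
  }
  out
}

## key collapsing localization isomers: residue string + termini + sorted
## modification codes (placement suffixes ignored)
localization_group <- function(sequences) {
  vapply(sequences, function(s) plain_key(parse_sequence(s)), "")
}

#' Aggregate feature intensities per oligonucleotide
#'
#' Sums intensities over charge/adduct states per replicate, and flags the
#' single (charge, adduct) variant with the lowest coefficient of variation
#' across replicates as the "best" representative for quantification.
#' Oligonucleotides differing only in modification localization are pooled
#' when `merge_localization = TRUE`.
#'
#' @param features Rows from [xic_quantify()], possibly several replicates.
#' @param merge_localization Pool localization isomers before aggregation?
#' @return List with `totals` (per oligo x replicate summed intensity) and
#'   `variants` (per oligo x charge x adduct: mean intensity, CV across
#'   replicates, `best` flag).
#' @export
aggregate_intensities <- function(features, merge_localization = TRUE) {
  f <- features
  f$group <- if (merge_localization) localization_group(f$sequence) else f$sequence
  # representative printable name per group (first sequence seen)
  name_of <- tapply(f$sequence, f$group, `[`, 1)
  tot <- stats::aggregate(intensity ~ group + replicate_id, data = f, FUN = sum)
  totals <- data.frame(sequence = unname(name_of[tot$group]),
                       replicate_id = tot$replicate_id,
                       intensity = tot$intensity, stringsAsFactors = FALSE)
  f$variant <- paste(f$group, f$charge, f$adduct, sep = "\r")
  agg <- stats::aggregate(intensity ~ variant + group + charge + adduct,
                          data = f, FUN = mean)
  cv <- tapply(f$intensity, f$variant, function(x) {
    if (length(x) < 2 || mean(x) == 0) return(Inf)
    stats::sd(x) / mean(x)
  })
  # constant nonzero series across >=2 replicates has CV 0; single-replicate
  # variants rank last (Inf) unless everything is single-replicate
  n_rep <- length(unique(f$replicate_id))
  if (n_rep < 2) cv[] <- vapply(names(cv), function(v) 0, 0)
  agg$cv <- as.numeric(cv[agg$variant])
  agg$best <- FALSE
  for (g in unique(agg$group)) {
    i <- which(agg$group == g)
    best <- i[order(agg$cv[i], -agg$intensity[i])][1]
    agg$best[best] <- TRUE
  }
  variants <- data.frame(sequence = unname(name_of[agg$group]),
                         charge = agg$charge, adduct = agg$adduct,
                         mean_intensity = agg$intensity, cv = agg$cv,
                         best = agg$best, stringsAsFactors = FALSE)
  list(totals = totals, variants = variants)
}
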