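#' Configuration for the synthetic-run simulator
#'
#' The simulator emulates a data-dependent negative-mode LC-MS/MS
#' acquisition of an RNase digest: oligonucleotides drawn from a digested
#' sequence database, fragmented in silico, with configurable modification
#' placement, salt adducts, isotopologue-offset precursor selection,
#' fragment dropout and noise peaks. Every run is deterministic for a given
#' seed and comes with a ground-truth table.
#'
#' @param records Parent FASTA records (data frame `id`, `sequence`);
#'   `NULL` generates `n_seqs` random sequences of `seq_length` nt.
#' @param n_seqs,seq_length Random-database parameters (defaults emulate a
#'   set of in vitro transcripts of lncRNA scale: 10 sequences of 340 nt).
#' @param seed Integer seed (mandatory).
#' @param n_spectra Number of MS2 spectra to simulate.
#' @param digestion,missed_cleavages,min_length,max_length In-silico
#'   digestion settings used to build the oligonucleotide pool.
#' @param variable_mods Modification codes available to the simulator.
#' @param site_mod_prob Probability that an eligible site carries a
#'   modification.
#' @param max_mods Cap on modifications per oligonucleotide.
#' @param adduct_fractions Named fractions of spectra carrying each salt
#'   adduct (e.g. `c(Na = 0.2, K = 0.1)`); remainder is adduct-free.
#' @param isotope_probs Named probabilities over the isotopologue offset k
#'   (names are integers, e.g. `c("0" = 0.7, "1" = 0.3)`).
#' @param charges Precursor charge states sampled (negative integers).
#' @param dropout Per-fragment dropout probability.
#' @param noise_peaks Number of random noise peaks per spectrum.
#' @param intensity_meanlog,intensity_sdlog Log-normal fragment intensity
#'   parameters.
#' @param noise_meanlog,noise_sdlog Log-normal noise intensity parameters.
#' @param scan_range MS1 scan range in Th; precursors are kept inside it.
#' @param rt_spacing Seconds between consecutive simulated MS2 spectra.
#' @param foreign_fraction Fraction of spectra generated from sequences
#'   absent from the database (unidentifiable ground truth), used for FDR
#'   calibration benchmarks.
#' @return A `sim_config` list.
#' @export
sim_config <- function(records = NULL, n_seqs = 10L, seq_length = 340L,
                       seed = 1L, n_spectra = 100L,
                       digestion = "rnase_t1", missed_cleavages = 1L,
                       min_length = 3L, max_length = 40L,
                       variable_mods = character(), site_mod_prob = 0.1,
                       max_mods = 2L,
                       adduct_fractions = c(Na = 0, K = 0),
                       isotope_probs = c("0" = 1),
                       charges = -2:-5, dropout = 0, noise_peaks = 0L,
                       intensity_meanlog = log(1e4), intensity_sdlog = 1,
                       noise_meanlog = log(1e2), noise_sdlog = 1,
                       scan_range = c(600, 3500), rt_spacing = 2,
                       foreign_fraction = 0) {
  stopifnot(!is.null(seed), all(adduct_fractions >= 0), sum(adduct_fractions) <= 1,
            all(isotope_probs >= 0), abs(sum(isotope_probs) - 1) < 1e-9,
            dropout >= 0, dropout <= 1, foreign_fraction >= 0,
            foreign_fraction <= 1, all(charges < 0))
  structure(as.list(environment()), class = "sim_config")
}

## random RNA parent sequences, uniform over A/C/G/U
random_rna_records <- function(n, len, prefix = "SIM") {
  data.frame(
    id = sprintf("%s_%03d", prefix, seq_len(n)),
    description = "synthetic random RNA",
    sequence = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
    }, ""),
    stringsAsFactors = FALSE
  )
}

## digest parents into the oligo pool the simulator draws from
.sim_pool <- function(records, config) {
  pool <- list()
  for (r in seq_len(nrow(records))) {
    parent <- parse_sequence(records$sequence[r])
    prods <- switch(config$digestion,
      rnase_t1 = digest_rnase_t1(parent, config$missed_cleavages,
                                 min_length = config$min_length,
                                 max_length = config$max_length,
                                 parent_id = records$id[r]),
      unspecific = digest_unspecific(parent, config$min_length,
                                     config$max_length,
                                     parent_id = records$id[r]),
      stop("unsupported simulator digestion: ", config$digestion))
    pool <- c(pool, prods)
  }
  if (!length(pool)) stop("digestion produced no oligonucleotides to simulate")
  pool
}

## place variable modifications on one oligo according to the config
.sim_modify <- function(seq, config) {
  placed <- 0L
  for (code in config$variable_mods) {
    row <- modification_registry(code)
    targets <- strsplit(row$targets, ",", fixed = TRUE)[[1]]
    sites <- which(seq$residues %in% targets & is.na(seq$mod_code))
    for (pos in sites) {
      if (placed >= config$max_mods) break
      if (stats::runif(1) < config$site_mod_prob) {
        pls <- mod_resolved_placements(code)
        if (length(pls) > 1 && pos == length(seq$residues)) pls <- "base"
        seq$mod_code[pos] <- code
        seq$mod_placement[pos] <- if (length(pls) > 1) sample(pls, 1) else pls
        placed <- placed + 1L
      }
    }
  }
  seq
}

#' Simulate one MS2 spectrum of a known oligonucleotide
#'
#' Peaks are the oligonucleotide's theoretical fragments (log-normal
#' intensities, optional dropout) plus uniform noise peaks; the precursor
#' m/z corresponds to the adducted, isotopologue-shifted species. Uses the
#' current RNG state; wrap in a seeded context for reproducibility.
#'
#' @param seq An `na_sequence`.
#' @param charge Precursor charge (negative integer).
#' @param adduct Cation composition string (`""` for none).
#' @param k Isotopologue offset (integer).
#' @param config A [sim_config()].
#' @param native_id,rt Spectrum metadata.
#' @return An `ms2_spectrum`.
#' @export
simulate_spectrum <- function(seq, charge, adduct = "", k = 0L,
                              config = sim_config(), native_id = "scan=1",
                              rt = 0) {
  frag <- generate_theoretical_spectrum(seq, ION_TYPES,
                                        fragment_charges_for(charge, 4L))
  keep <- stats::runif(nrow(frag)) >= config$dropout
  mz <- frag$mz[keep]
  inten <- stats::rlnorm(sum(keep), config$intensity_meanlog,
                         config$intensity_sdlog)
  if (config$noise_peaks > 0) {
    mz <- c(mz, stats::runif(config$noise_peaks, config$scan_range[1],
                             config$scan_range[2]))
    inten <- c(inten, stats::rlnorm(config$noise_peaks, config$noise_meanlog,
                                    config$noise_sdlog))
  }
  m_obs <- sequence_mass(seq) + k * mass_constants[["neutron"]] +
    (if (nzchar(adduct)) adduct_mass_shift(adduct) else 0)
  ms2_spectrum(native_id, rt, mz_from_mass(m_obs, charge), charge, mz, inten)
}

#' Simulate a full run with ground truth
#'
#' Draws `n_spectra` oligonucleotides from the digested database (or, for a
#' `foreign_fraction` of spectra, from a database of equally sized random
#' sequences that is NOT part of the returned records), places
#' modifications, samples charge/adduct/isotopologue offset, and simulates
#' each spectrum. Optionally writes the run to mzML and the truth table to
#' TSV.
#'
#' @param config A [sim_config()].
#' @param mzml_path,truth_path Optional output file paths.
#' @return List with `run` (an `ms_run`), `truth` (data frame:
#'   `spectrum_id`, `sequence`, `charge`, `adduct`, `k`, `identifiable`)
#'   and `records` (the parent FASTA records forming the search database).
#' @export
simulate_run <- function(config, mzml_path = NULL, truth_path = NULL) {
  out <- with_seed(config$seed, {
    records <- config$records
    if (is.null(records)) {
      records <- random_rna_records(config$n_seqs, config$seq_length)
    }
    pool <- .sim_pool(records, config)
    foreign_pool <- NULL
    if (config$foreign_fraction > 0) {
      foreign_records <- random_rna_records(config$n_seqs, config$seq_length,
                                            prefix = "FOREIGN")
      foreign_pool <- .sim_pool(foreign_records, config)
    }
    add_names <- names(config$adduct_fractions)
    add_probs <- c(1 - sum(config$adduct_fractions), config$adduct_fractions)
    k_vals <- as.integer(names(config$isotope_probs))
    spectra <- vector("list", config$n_spectra)
    truth <- vector("list", config$n_spectra)
    for (i in seq_len(config$n_spectra)) {
      foreign <- config$foreign_fraction > 0 &&
        stats::runif(1) < config$foreign_fraction
      src <- if (foreign) foreign_pool else pool
      # data-dependent acquisition only selects precursors inside the MS1
      # scan range: redraw until some charge state fits
      for (try in 1:1000) {
        prod <- src[[sample.int(length(src), 1L)]]
        seq <- .sim_modify(prod$sequence, config)
        mass <- sequence_mass(seq)
        mzs <- mz_from_mass(mass, config$charges)
        ok <- config$charges[mzs >= config$scan_range[1] &
                             mzs <= config$scan_range[2]]
        if (length(ok)) break
      }
      if (!length(ok)) {
        stop("no digestion product fits the scan range at the configured charges")
      }
      z <- sample(rep(ok, 2L), 1L)
      adduct <- sample(c("", add_names), 1L, prob = add_probs)
      k <- if (length(k_vals) == 1L) k_vals else
        sample(k_vals, 1L, prob = as.numeric(config$isotope_probs))
      id <- sprintf("scan=%d", i)
      spectra[[i]] <- simulate_spectrum(seq, z, adduct, k, config, id,
                                        rt = i * config$rt_spacing)
      truth[[i]] <- data.frame(spectrum_id = id, sequence = format(seq),
                               charge = z, adduct = adduct, k = k,
                               identifiable = !foreign,
                               stringsAsFactors = FALSE)
    }
    list(run = structure(list(ms1 = list(), ms2 = spectra), class = "ms_run"),
         truth = do.call(rbind, truth), records = records)
  })
  if (!is.null(mzml_path)) write_mzml(out$run, mzml_path)
  if (!is.null(truth_path)) {
    utils::write.table(out$truth, truth_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  out
}

#' FDR-calibration benchmark run
#'
#' Convenience wrapper around [simulate_run()]: a configured fraction of
#' spectra derive from sequences absent from the search database, so the
#' truth table labels each spectrum identifiable/unidentifiable and the
#' empirical false-match fraction of any accepted set can be measured.
#'
#' @param config A [sim_config()] with `foreign_fraction > 0`.
#' @inheritParams simulate_run
#' @return See [simulate_run()].
#' @export
make_calibration_benchmark <- function(config, mzml_path = NULL,
                                       truth_path = NULL) {
  if (config$foreign_fraction <= 0) {
    stop("calibration benchmark needs foreign_fraction > 0")
  }
  simulate_run(config, mzml_path, truth_path)
}

#' Simulate an MS1 map with rectangular elution profiles
#'
#' For quantification tests: each feature elutes as a rectangular profile
#' of the given total intensity, split evenly across the scans inside its
#' RT window, at its m/z (monoisotopic only).
#'
#' @param features Data frame with `mz`, `rt_center`, `rt_width`,
#'   `total_intensity`.
#' @param rt_range Run RT span in seconds. @param scan_interval Seconds
#'   between MS1 scans.
#' @return An `ms_run` containing only MS1 scans.
#' @export
simulate_ms1_profile <- function(features, rt_range = c(0, 600),
                                 scan_interval = 2) {
  rts <- seq(rt_range[1], rt_range[2], by = scan_interval)
  ms1 <- lapply(seq_along(rts), function(si) {
    rt <- rts[si]
    mz <- numeric(); inten <- numeric()
    for (i in seq_len(nrow(features))) {
      lo <- features$rt_center[i] - features$rt_width[i] / 2
      hi <- features$rt_center[i] + features$rt_width[i] / 2
      if (rt >= lo && rt <= hi) {
        n_scans <- sum(rts >= lo & rts <= hi)
        mz <- c(mz, features$mz[i])
        inten <- c(inten, features$total_intensity[i] / n_scans)
      }
    }
    ord <- order(mz)
    list(native_id = sprintf("ms1=%d", si), rt = rt, mz = mz[ord],
         intensity = inten[ord])
  })
  structure(list(ms1 = ms1, ms2 = list()), class = "ms_run")
}
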