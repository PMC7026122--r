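# oligosearch

**oligosearch** is an R implementation of a database search engine for RNA
oligonucleotide tandem mass spectrometry — the MS/MS analogue of shotgun
proteomics, applied to the epitranscriptome. Given negative-mode MS2
spectra of an RNase digest and a FASTA database of candidate RNA
sequences, it identifies which (modified) oligonucleotide generated each
spectrum, localizes modifications at single-nucleotide resolution, and
attaches target/decoy false-discovery-rate estimates to the results.

It is aimed at researchers mapping post-transcriptional modifications
(m5C, 2'-O-methylation, t6A, mcm5s2U, ...) on tRNA, rRNA, or in vitro
transcripts by LC-MS/MS, and at method developers who need a fully
scriptable, statistically grounded alternative to manual spectrum
inspection.

## What it computes

* **In-silico digestion.** RNase T1 cleavage (3' of G, leaving 5'-OH /
  3'-phosphate products) with missed cleavages, or unspecific cleavage for
  synthesis ladders. Variable modifications are enumerated combinatorially
  (up to a per-oligo cap), with base- vs. ribose-placement variants kept as
  distinct candidates because they change a-B ion masses.
* **Theoretical spectra.** All nine fragment series of the standard
  nucleic-acid nomenclature. With `c_i` the 5' fragment of `i` residues
  carrying a 3'-phosphate and `w_j` the 3' fragment of `j` residues
  carrying a 5'-phosphate:

      d = c + H2O    b = c − HPO3    a = b − H2O    a-B = a − base(i)
      x = w − H2O    y = w − HPO3    z = y − H2O

  so that `c_i + y_{n−i} = M + H2O` for every cleavage site.
* **Precursor correction.** The experimental neutral mass
  `M = |z|·(m/z) + |z|·m_p` is compared with candidates after subtracting
  `k` neutron masses (isotopologue offsets, `k = −1 … 3` typical) and any
  salt-adduct shift (`Na⁺: +21.98194 Da`, `K⁺: +37.95588 Da` — one cation
  replacing one backbone proton), at ppm tolerance.
* **Scoring.** A hyperscore variant:
  `ln(1 + Σ I_matched) + ln(N_f!) + ln(N_r!)`, with `N_f`/`N_r` the counts
  of matched 5'-series and 3'-series ions.
* **Validation.** Spectrum-level q-values from shuffled/reversed decoys:
  `FDR(s) = #decoys ≥ s / max(1, #targets ≥ s)`, monotonized; plus
  single-hit removal, sequence coverage, per-modification spectral counts,
  and a majority-replicate "effective FDR".
* **Quantification.** Export of (formula, charge, adduct, median RT)
  target coordinates at an FDR cutoff, a simple windowed XIC integrator
  for MS1 maps, and charge/adduct aggregation with best-variant selection
  by cross-replicate CV.
* **Simulation.** A seeded generator producing mzML-compatible runs with
  ground truth (modifications, adducts, isotopologue offsets, dropout,
  noise, unidentifiable "foreign" spectra), so the whole pipeline is
  testable without instrument data.

## Worked example

Simulate a two-transcript RNase T1 run with partial 5-methylcytidine
modification, sodium adducts, noise, and 25% spectra from sequences
outside the database; then search it against a target/decoy database:

```r
library(oligosearch)

cfg <- sim_config(n_seqs = 2, seq_length = 200, seed = 42, n_spectra = 80,
                  variable_mods = "m5C", site_mod_prob = 0.15, max_mods = 2,
                  dropout = 0.3, noise_peaks = 40, foreign_fraction = 0.25,
                  adduct_fractions = c(Na = 0.15),
                  isotope_probs = c("0" = 0.7, "1" = 0.3))
sim <- make_calibration_benchmark(cfg)

records <- rbind(sim$records, generate_decoys(sim$records, "shuffle", seed = 1))
sc <- search_config(adducts = "Na", isotope_offsets = 0:3,
                    variable_mods = "m5C", max_mods = 2, missed_cleavages = 1)
db <- build_candidate_db(records, sc)
db
#> <candidate_db> 2008 candidates (1085 decoy), mass range 933.18-7925.09 Da

osms <- compute_qvalues(search_run(sim$run, db, sc))
ids <- filter_fdr(osms, 0.05)
head(ids[, c("spectrum_id", "sequence", "charge", "adduct", "k",
             "hyperscore", "q_value")], 5)
#>    spectrum_id              sequence charge adduct k hyperscore q_value
#> 7       scan=9    CCUUUCCAUAUCUCGUGp     -5        1     1778.8       0
#> 17     scan=23     CAUAUCACGCCUCCCGp     -5     Na 0     1701.6       0
#> 10     scan=13 GCCUUUCCAUAU[m5C]UCGp     -5        0     1590.4       0
#> 20     scan=26    CAUCACAAAGCCUCAAGp     -4        0     1219.7       0
#> 67     scan=75        AAUCUUGCACUCGp     -4        0      883.3       0
```

Each row is an oligonucleotide-spectrum match: the sequence in bracket
notation (`[m5C]` marks a modified residue, trailing `p` the 3'-phosphate
left by RNase T1), the precursor charge, the annotated salt adduct and
isotopologue offset `k`, the hyperscore, and the q-value at which the
match is accepted. Downstream summaries:

```r
sapply(sequence_coverage(ids, sim$records), function(x) x$coverage_fraction)
#> SIM_001 SIM_002
#>    0.67    0.66
aggregate_modification_report(ids)
#>   search_code spectral_count
#> 1         m5C             20
```

Command-line wrappers for the simulate / decoy / search steps live in
`inst/scripts/` (`simulate.R`, `make-decoys.R`, `search.R`), taking JSON
configuration files mirroring `sim_config()` / `search_config()`.

## Scope notes

Monoisotopic masses and negative ion mode only; no neutral-loss or
internal fragments; no cross-run retention-time alignment; the XIC
quantifier is deliberately simple (the export format, not feature
detection, is the contract). See `vignettes/oligosearch-methods.Rmd` for
the model, parameter defaults, numerical choices, and limitations.
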