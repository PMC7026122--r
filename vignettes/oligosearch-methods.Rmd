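---
title: "Methods: identifying modified RNA oligonucleotides from tandem MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying modified RNA oligonucleotides from tandem MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligosearch)
```

## The problem and the model

Post-transcriptional RNA modifications can be located at single-nucleotide
resolution by fragmenting intact oligonucleotides in a mass spectrometer
and comparing the resulting MS2 spectra against a sequence database — the
same shotgun strategy used for peptides, transplanted to nucleic acids.
`oligosearch` implements that pipeline: in-silico digestion of an RNA
FASTA database, enumeration of variably modified candidates, theoretical
fragment generation, precursor-indexed candidate lookup with salt-adduct
and isotopologue correction, hyperscore matching, and target/decoy
q-value estimation, plus a simulator that makes the whole chain testable
without instrument data.

The model assumes high-resolution, centroided, negative-mode data (a few
ppm mass accuracy), oligonucleotides that ionize by deprotonation, and a
digest dominated by one endonuclease chemistry. All masses are
monoisotopic; average-mass searches are out of scope.

## Mass bookkeeping

A sequence is a chain of nucleosides joined by phosphodiester linkages:
each internal linkage contributes HPO3 and removes H2O. Terminal
chemistry is explicit: 5'-OH or 5'-phosphate, and 3'-OH, 3'-phosphate or
2',3'-cyclic phosphate (RNase T1 leaves 5'-OH / 3'-phosphate products;
the cyclic intermediate is supported but off by default, since mature
digests show the open form). Modifications are mass-shift classes keyed
by a search code (e.g. `mC?` = any cytidine monomethylation), stored in a
user-extensible registry (`inst/extdata/modifications.tsv`) with the
shift formula, the eligible bases, and the represented isobaric
modifications.

Three constants are kept deliberately distinct: the proton mass
(1.007276 Da) for charge bookkeeping in m/z conversions, the neutron mass
(1.008665 Da) for isotopologue precursor offsets, and the C13–C12
difference (1.00335 Da) for the peak spacing used in deisotoping. They
are numerically close but physically different corrections.

## Modification placement and a-B ions

The a-B ion — an a-type fragment that has also lost the nucleobase at the
cleavage-site residue — is the only series whose mass depends on whether
a modification sits on the base or on the ribose. The registry therefore
carries a placement attribute:

* `base` or `sugar`: fixed placement (`m5C`, `Um`).
* `either` (codes ending in `?`): both placements are chemically
  plausible and are enumerated as **distinct candidates** with identical
  precursor mass. They are emitted separately only where an a-B ion can
  discriminate them, i.e. at any position except the 3'-terminal residue
  (no a-B ion covers position *n*).
* `split`: modifications with a fixed part on each moiety, e.g.
  `mcm5Um` (mcm5 on the base, 2'-O-methyl on the ribose) or `hm5Cm`.
  The a-B ion subtracts only the base-located portion. This is a small
  extension beyond the three-valued placement of the original design; a
  single resolved placement would mis-state a-B masses for these combined
  modifications by a methyl group.

For `either` codes with a structural split in one isoform (the
`ac4C/f5Cm?` class), the sugar-resolved variant uses the registry's
`sugar_part` (the 2'-O-methyl of f5Cm) and leaves the formyl remainder on
the base.

When the top match ties in hyperscore with a placement isomer (same
residues, same modification multiset, different site or moiety), the
reported match is flagged `localization_ambiguous` — the spectrum simply
lacks the discriminating peaks.

## Digestion and candidate space

RNase T1 cleaves 3' of guanosine. Modified guanosines are cleaved by
default (`cleave_modified_g = TRUE`): identified oligonucleotides ending
in methylated G are routinely observed, so a hard block would be wrong,
but the behaviour is configurable because T1 kinetics on modified G are
not established. Unspecific cleavage (synthesis ladders) enumerates all
substrings within length bounds, with 5'-OH/3'-OH on internal substrings
and parent termini at the ends.

The digestion *functions* default to no length bound (their contract is
the cleavage rule), while `search_config()` applies a practical default
of 3–40 nt: shorter products are uninformative (few fragments, massive
ambiguity) and longer ones exceed the usable precursor range. Candidates
identical in sequence, modification state and termini are stored once
with all parent locations, so multi-mapping oligonucleotides can credit
every locus in coverage reports (or be excluded via `unique_only`).

## Precursor correction and scoring

For a precursor of charge *z*, the experimental neutral mass is
`|z|·(m/z) + |z|·m_p`. Instrument software frequently selects a heavier
isotopologue of long oligonucleotides — and occasionally reports a
selected-ion m/z *below* the monoisotopic peak — so candidate lookup
subtracts `k` neutron masses for `k` in a configured window (typically
−1…3 or 0…4). Salt adducts are handled in the same comparison: a cation
replacing a backbone proton shifts the neutral mass by
`m(cation) − m(H)`; configured adducts and offsets combine freely, since
adducted, offset species co-occur in real maps. Among the (adduct, k)
combinations that explain the same candidate, the annotation with the
smallest absolute ppm error is reported. Unknown precursor charges are
resolved by iterating a configured charge range and keeping the
best-scoring assignment.

Fragment charges run from −1 down to `precursor_charge + 1`, capped at −4
by default — a fragment cannot retain all charges of its precursor, and
charges beyond −4 contribute little at these lengths.

The score is a hyperscore variant:

    ln(1 + sum of matched intensities) + ln(Nf!) + ln(Nr!)

with factorials via `lgamma`. Intensities enter as stored (`raw`), which
puts scores in the hundreds-to-thousands range on realistic intensity
scales; a `base_peak` normalization mode is available as a configuration
switch since the normalization convention of hyperscore implementations
varies. Peak matching assigns each experimental peak to the nearest
theoretical fragment within the ppm tolerance; equidistant ties go to the
lower-m/z fragment, and each fragment is matched by at most one peak (the
closest). Ranking ties break by fewer modifications, then lexicographic
sequence — determinism is part of the contract, and results are invariant
to spectrum order.

## Target/decoy validation

Decoys are per-target shuffles or reversals (length and composition
preserved; bracketed modification tokens travel with their residue).
q-values are computed at spectrum-match level over rank-1 matches:
`FDR(s) = #decoys ≥ s / max(1, #targets ≥ s)`, monotonized from the
bottom of the score list and capped at 1. The simple ratio is used
without a +1 correction: with thousands of matches the difference is
negligible, and the calibration test below measures the estimator as
implemented. Decoy matches are annotated but excluded from reported
lists. Utilities implement the common post-filters: q-value cutoff,
single-hit removal (per run), majority-replicate filtering with an
"effective FDR" recomputed as the decoy/target ratio among survivors.

## The simulator: what it emulates, what it does not

`sim_config()` describes a stated world: random (or supplied) parent
sequences digested by the configured rule; per-site modification
probability with a per-oligo cap; fractions of spectra carrying Na/K
adducts; a distribution over isotopologue offsets; log-normal fragment
intensities; per-fragment dropout; uniform noise peaks; and a 600–3500
m/z precursor scan range matching a typical acquisition — oligonucleotides
that cannot reach that window at the configured charges are never
selected, as in data-dependent acquisition. Defaults emulate an in vitro
transcript experiment: 10 parents of 340 nt, charges −2…−5, noise-free
unless stated.

For FDR calibration the benchmark adds a fraction of spectra simulated
from *foreign* parents — random sequences of the same size that are not
in the search database — so every accepted match can be labelled true or
false against ground truth. Foreign spectra produce chance matches
through composition collisions (distinct short oligonucleotides with
identical elemental composition are common), which is exactly the error
mode decoys are meant to model.

The simulator does **not** model chromatography (elution shape, co-
isolation, chimeric spectra), intensity structure tied to fragmentation
chemistry, electron transfer between series, or instrument-specific
artefacts. A green end-to-end test therefore establishes that the
engine's bookkeeping (masses, corrections, ranking, FDR mechanics) is
correct under the stated world; it does not certify identification rates
on real instrument data.

## Numerical and design choices

* Tolerances are relative (ppm) against the theoretical mass; index range
  queries are exact binary-search equivalents of a linear scan.
* Monoisotopic atomic masses are CODATA values hard-coded to 11 decimal
  places; registry shifts are validated against direct elemental
  evaluation in the tests (1e-4 Da).
* Deisotoping collapses a chain onto its lightest member, sums the
  cluster intensity (signal conservation), and annotates the inferred
  charge; it never increases peak count and is order-stable.
* Degenerate inputs: empty spectra pass through preprocessing; spectra
  without precursors are skipped and counted; an empty candidate database
  is an error; single-residue sequences cannot fragment and say so.
* Configuration files for the CLI wrappers are JSON rather than YAML —
  no YAML parser is among the package's dependencies, and JSON is
  loss-free for the flat parameter lists involved.
* The mzML layer is a minimal reader/writer (uncompressed 32/64-bit float
  arrays, centroided spectra) built on `xml2`: enough for vendor-converted
  files of that shape and for the simulator's fixtures, chosen over a
  heavyweight dependency that is not available in the target environment.

## Limitations

Neutral losses, internal fragments and base-loss satellites of w/y ions
are not generated. Oligonucleotide-level (as opposed to spectrum-level)
FDR is not implemented. Quantification integrates a fixed RT window
around the identification's median RT at the target m/z (monoisotopic
plus two isotopologues) — no trace building, no elution-model fit, no
cross-run alignment; its contract is the exported target table, and the
linearity of the integrator is what the tests establish. Positive ion
mode and average masses are out of scope.
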