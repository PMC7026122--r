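Package: oligosearch
Title: Database Search Engine for RNA Oligonucleotide Tandem Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identification of (modified) RNA oligonucleotides from
    negative-mode LC-MS/MS data by sequence database searching. Provides
    in-silico RNase digestion with variable-modification enumeration,
    theoretical fragment generation for the nine standard nucleic acid ion
    series (a-B, a, b, c, d, w, x, y, z), precursor matching with salt-adduct
    and isotopologue-offset correction, hyperscore-based spectrum scoring,
    target/decoy q-value estimation, sequence coverage and modification
    reporting, export of label-free quantification targets with a simple
    targeted XIC quantifier, and a synthetic-run simulator (mzML plus ground
    truth) for end-to-end testing without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
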