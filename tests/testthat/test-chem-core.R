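test_that("formula parsing, arithmetic and mass computation", {
  expect_equal(formula_mass("H2O"), 18.01056, tolerance = 1e-6)
  expect_equal(formula_mass("CH2"), 14.01565, tolerance = 1e-6)
  expect_equal(formula_mass(chem_formula("")), 0.0)
  # negative counts express difference formulas
  expect_equal(formula_mass("H-1N-1O"), 0.98402, tolerance = 1e-5)
  # arithmetic is associative/commutative and cancels exactly
  a <- chem_formula("C9H13N3O5"); b <- chem_formula("CH2"); c <- chem_formula("HPO3")
  expect_identical(format_formula((a + b) + c), format_formula(a + (c + b)))
  expect_identical(format_formula(a + b - b), format_formula(a))
  expect_error(chem_formula("C2Xx3"), "unsupported element")
})

test_that("m/z conversions are negative-mode and invert exactly", {
  expect_equal(mz_from_mass(1000, -1L), 998.992724, tolerance = 1e-9)
  expect_equal(mz_from_mass(1000, -2L), 498.992724, tolerance = 1e-9)
  expect_error(mz_from_mass(1000, 1L), "negative")
  expect_error(mass_from_mz(500, 0L), "negative")
  for (M in c(500.123, 3206.44254, 12000.5)) {
    for (z in -1:-7) {
      expect_equal(mass_from_mz(mz_from_mass(M, z), z), M, tolerance = 1e-9 * M)
    }
  }
})

test_that("salt adduct shifts replace backbone protons", {
  expect_equal(adduct_mass_shift("Na"), 21.98194, tolerance = 1e-5)
  expect_equal(adduct_mass_shift("K"), 37.95588, tolerance = 1e-5)
  expect_equal(adduct_mass_shift("NaK"), 21.98194 + 37.95588, tolerance = 1e-5)
  expect_equal(adduct_mass_shift("Na2K"),
               2 * adduct_mass_shift("Na") + adduct_mass_shift("K"),
               tolerance = 1e-9)
  expect_error(adduct_mass_shift("C2"), "unsupported adduct")
  expect_error(adduct_mass_shift(chem_formula("")), "at least one cation")
})

test_that("sequence masses match the elemental oracle", {
  expect_equal(sequence_mass(parse_sequence("C")), 243.08552, tolerance = 1e-5)
  expect_equal(sequence_mass(parse_sequence("CG")), 588.13297, tolerance = 1e-5)
  # methylation shift
  d <- sequence_mass(parse_sequence("UAAC[m5C]CAAUGp")) -
    sequence_mass(parse_sequence("UAACCCAAUGp"))
  expect_equal(d, 14.01565, tolerance = 1e-5)
  # random sequences against the atom-counting oracle
  set.seed(101)
  for (i in 1:20) {
    res <- sample(c("A", "C", "G", "U"), sample(2:15, 1), replace = TRUE)
    s <- na_sequence(res)
    expect_equal(sequence_mass(s), oracle_oligo_mass(res), tolerance = 1e-9)
    expect_equal(sequence_mass(s), formula_mass(sequence_formula(s)),
                 tolerance = 1e-9)
  }
})

test_that("terminus chemistry adjusts the mass as phosphate bookkeeping", {
  base <- sequence_mass(parse_sequence("AUGC"))
  hpo3 <- formula_mass("HPO3"); h2o <- formula_mass("H2O")
  expect_equal(sequence_mass(parse_sequence("pAUGC")), base + hpo3, tolerance = 1e-9)
  expect_equal(sequence_mass(parse_sequence("AUGCp")), base + hpo3, tolerance = 1e-9)
  expect_equal(sequence_mass(parse_sequence("AUGC>p")), base + hpo3 - h2o,
               tolerance = 1e-9)
})

test_that("sequence mass is additive under phosphodiester joining", {
  set.seed(77)
  for (i in 1:10) {
    r1 <- sample(c("A", "C", "G", "U"), sample(2:8, 1), replace = TRUE)
    r2 <- sample(c("A", "C", "G", "U"), sample(2:8, 1), replace = TRUE)
    joined <- sequence_mass(na_sequence(c(r1, r2)))
    parts <- sequence_mass(na_sequence(r1)) + sequence_mass(na_sequence(r2))
    expect_equal(joined, parts - formula_mass("H2O") + formula_mass("HPO3"),
                 tolerance = 1e-9)
  }
})

test_that("modification registry is consistent", {
  reg <- modification_registry()
  expect_true(all(reg$mass_shift > -200 & reg$mass_shift < 500))
  expect_identical(grepl("\\?$", reg$code), reg$placement == "either")
  # spot checks against independently computed shifts
  expect_equal(modification_registry("t6A")$mass_shift, 145.03751, tolerance = 1e-5)
  expect_equal(modification_registry("mcm5s2U")$mass_shift, 87.99829, tolerance = 1e-5)
  expect_equal(modification_registry("I")$mass_shift, 0.98402, tolerance = 1e-5)
  expect_equal(modification_registry("yW")$mass_shift, 225.10011, tolerance = 1e-5)
  # every registry shift agrees with direct atom-count evaluation to 1e-4
  for (i in seq_len(nrow(reg))) {
    f <- chem_formula(reg$formula[i])
    direct <- sum(oracle_masses[names(f)] * as.numeric(f))
    expect_equal(reg$mass_shift[i], direct, tolerance = 1e-4)
  }
  expect_error(modification_registry("nope"), "unknown modification")
})

test_that("either-placement variants share precursor mass but differ in a-B", {
  reg <- modification_registry()
  for (code in reg$code[reg$placement == "either"]) {
    tgt <- strsplit(reg$targets[reg$code == code], ",")[[1]][1]
    res <- c("A", "U", tgt, "G", "C")
    sb <- na_sequence(res, c(NA, NA, code, NA, NA), c(NA, NA, "base", NA, NA))
    ss <- na_sequence(res, c(NA, NA, code, NA, NA), c(NA, NA, "sugar", NA, NA))
    expect_equal(sequence_mass(sb), sequence_mass(ss), tolerance = 1e-9)
    ab_b <- fragment_neutral_mass(sb, "a-B", 3)
    ab_s <- fragment_neutral_mass(ss, "a-B", 3)
    expect_gt(abs(ab_b - ab_s), 1e-3)
    # non-discriminating series are identical
    for (ty in c("w", "x", "y", "z", "c", "d")) {
      expect_equal(fragment_neutral_mass(sb, ty, 2),
                   fragment_neutral_mass(ss, ty, 2), tolerance = 1e-9)
    }
  }
})

test_that("sequence validation rejects bad input", {
  expect_error(na_sequence(character()), "at least one residue")
  expect_error(na_sequence(c("A", "X")), "illegal residue")
  expect_error(na_sequence("A", "m5C"), "cannot be placed")
  expect_error(parse_sequence("AU[nope]G"), "unknown modification")
  # round trip through the printed notation
  for (s in c("UAAC[m5C]CAAUGp", "pAUGC", "A[mC?/s]U[mC?/b]CA[mG?/b]G>p")) {
    expect_identical(format(parse_sequence(s)), s)
  }
})
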