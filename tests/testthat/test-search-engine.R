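# small helper: a candidate db built straight from records
small_db <- function(seqs, cfg = search_config(digestion = "none", max_mods = 0,
                                               min_length = 1)) {
  recs <- data.frame(id = paste0("s", seq_along(seqs)), description = "",
                     sequence = seqs, stringsAsFactors = FALSE)
  build_candidate_db(recs, cfg)
}

test_that("precursor mapping applies isotopologue and adduct corrections", {
  # one candidate of known mass; craft spectra around it
  db <- small_db("AUGCAUGC")
  M <- db$table$mass[1]
  mk <- function(m_exp, z = -2L) ms2_spectrum("s", 1, mz_from_mass(m_exp, z), z)
  neutron <- mass_constants[["neutron"]]
  cfg <- search_config(isotope_offsets = 0:4, digestion = "none")
  hit <- find_candidates(mk(M + neutron), db, cfg)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$k, 1L)
  expect_lt(abs(hit$ppm_error), 0.01)
  cfg_na <- search_config(adducts = "Na", isotope_offsets = 0L, digestion = "none")
  hit2 <- find_candidates(mk(M + adduct_mass_shift("Na")), db, cfg_na)
  expect_equal(nrow(hit2), 1L)
  expect_identical(hit2$adduct, "Na")
  expect_identical(hit2$k, 0L)
  # 5 ppm off at 3 ppm tolerance: no match
  cfg0 <- search_config(isotope_offsets = 0L, digestion = "none")
  expect_equal(nrow(find_candidates(mk(M * (1 + 5e-6)), db, cfg0)), 0L)
  expect_equal(nrow(find_candidates(mk(M * (1 + 2e-6)), db, cfg0)), 1L)
})

test_that("index range query equals brute-force scan", {
  set.seed(33)
  seqs <- vapply(1:80, function(i)
    paste(sample(c("A", "C", "G", "U"), sample(3:12, 1), replace = TRUE),
          collapse = ""), "")
  db <- small_db(unique(seqs))
  for (i in 1:50) {
    q <- runif(1, min(db$table$mass) - 10, max(db$table$mass) + 10)
    tol <- sample(c(3, 10, 1000), 1)
    got <- query_mass_index(db, q, tol)
    want <- which(abs(q - db$table$mass) / db$table$mass <= tol * 1e-6)
    expect_identical(got, if (length(want)) want else integer())
  }
})

test_that("peak matching respects tolerance, ties and uniqueness", {
  frag <- data.frame(ion_type = c("y", "c", "w"), index = 1:3, charge = -1L,
                     neutral_mass = 0, mz = c(500.0000, 500.0008, 800.0))
  mk <- function(mz, inten = rep(1, length(mz)))
    ms2_spectrum("s", 1, 900, -2L, mz, inten)
  m <- match_peaks(mk(500.0005), frag, 3)
  expect_equal(nrow(m), 1L)
  m2 <- match_peaks(mk(500.005), frag, 3)   # 10 ppm away
  expect_equal(nrow(m2), 0L)
  # tie at equidistance goes to the lower-m/z fragment
  m3 <- match_peaks(mk(500.0004), frag, 3)
  expect_identical(m3$fragment, 1L)
  # each fragment matched at most once: closest of two peaks wins
  m4 <- match_peaks(mk(c(799.9995, 800.0001)), frag, 3)
  expect_equal(nrow(m4), 1L)
  expect_equal(m4$mz, 800.0001)
})

test_that("hyperscore closed form and monotonicity", {
  m <- data.frame(intensity = rep(1, 10),
                  ion_type = c(rep("c", 5), rep("y", 5)))
  expect_equal(hyperscore(m), log(11) + 2 * log(factorial(5)), tolerance = 1e-9)
  expect_equal(hyperscore(m), 11.9729, tolerance = 1e-4)
  expect_equal(hyperscore(m[0, ]), 0.0)
  # removing a matched peak never increases the score
  set.seed(4)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    m <- data.frame(intensity = rlnorm(n),
                    ion_type = sample(c("a-B", "a", "b", "c", "d", "w", "x", "y", "z"),
                                      n, replace = TRUE))
    drop <- sample(n, 1)
    expect_lte(hyperscore(m[-drop, , drop = FALSE]), hyperscore(m))
  }
})

test_that("noise-free self-search recovers the candidate at rank 1", {
  cfg <- sim_config(n_seqs = 2, seq_length = 120, seed = 50, n_spectra = 15,
                    variable_mods = "m5C", site_mod_prob = 0.2, max_mods = 2)
  sim <- simulate_run(cfg)
  sc <- search_config(variable_mods = "m5C", max_mods = 2, missed_cleavages = 1)
  db <- build_candidate_db(sim$records, sc)
  osms <- search_run(sim$run, db, sc)
  r1 <- osms[osms$rank == 1, ]
  m <- merge(r1, sim$truth, by = "spectrum_id")
  expect_equal(nrow(m), 15L)
  expect_identical(m$sequence.x, m$sequence.y)
  expect_true(all(m$hyperscore > 0))
  expect_true(all(abs(m$precursor_error_ppm) <= 3))
})

test_that("search is deterministic and independent of spectrum order", {
  cfg <- sim_config(n_seqs = 2, seq_length = 100, seed = 60, n_spectra = 10)
  sim <- simulate_run(cfg)
  sc <- search_config(max_mods = 0, missed_cleavages = 1)
  db <- build_candidate_db(sim$records, sc)
  o1 <- search_run(sim$run$ms2, db, sc)
  o2 <- search_run(rev(sim$run$ms2), db, sc)
  key <- function(o) o[order(o$spectrum_id, o$rank), ]
  k1 <- key(o1); k2 <- key(o2)
  rownames(k1) <- rownames(k2) <- NULL
  attr(k1, "log") <- attr(k2, "log") <- NULL
  expect_identical(k1, k2)
})

test_that("missing discriminating peaks flag ambiguous localization", {
  # two C sites; simulate a spectrum from the base-methylated candidate but
  # remove every a-B peak, so the two placement isomers tie
  recs <- data.frame(id = "p", description = "", sequence = "ACAUCAAG",
                     stringsAsFactors = FALSE)
  sc <- search_config(variable_mods = "mC?", max_mods = 1,
                      missed_cleavages = 0, min_length = 3)
  db <- build_candidate_db(recs, sc)
  truth <- parse_sequence("A[mC?/b]AUCAAG")   # parent is its own T1 product
  frag <- generate_theoretical_spectrum(truth, setdiff(ION_TYPES, "a-B"), -1L)
  sp <- ms2_spectrum("amb", 1, mz_from_mass(sequence_mass(truth), -2L), -2L,
                     frag$mz, rep(100, nrow(frag)))
  osm <- search_run(list(sp), db, sc)
  expect_true(osm$localization_ambiguous[osm$rank == 1])
  # with the full ion set simulated, localization is unambiguous
  frag2 <- generate_theoretical_spectrum(truth, ION_TYPES, -1L)
  sp2 <- ms2_spectrum("ok", 1, mz_from_mass(sequence_mass(truth), -2L), -2L,
                      frag2$mz, rep(100, nrow(frag2)))
  osm2 <- search_run(list(sp2), db, sc)
  expect_identical(osm2$sequence[osm2$rank == 1], format(truth))
  expect_false(osm2$localization_ambiguous[osm2$rank == 1])
})

test_that("unknown precursor charge is resolved by iteration", {
  recs <- data.frame(id = "p", description = "", sequence = "AUGCAUGCAUAG",
                     stringsAsFactors = FALSE)
  sc <- search_config(max_mods = 0, missed_cleavages = 0, min_length = 3,
                      digestion = "none", precursor_charges = -2:-5)
  db <- build_candidate_db(recs, sc)
  truth <- db$sequences[[1]]
  frag <- generate_theoretical_spectrum(truth, ION_TYPES, -1:-2)
  sp <- ms2_spectrum("u", 1, mz_from_mass(sequence_mass(truth), -3L), 0L,
                     frag$mz, rep(10, nrow(frag)))
  osm <- search_run(list(sp), db, sc)
  expect_identical(osm$charge[1], -3L)
  expect_identical(osm$sequence[1], db$table$key[1])
})
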