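test_that("FASTA reading validates and round-trips", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x first record", "AUGC", ">y", "AUG[m5C]CAAG"), path)
  recs <- read_fasta(path)
  expect_equal(nrow(recs), 2L)
  expect_identical(recs$id, c("x", "y"))
  expect_identical(recs$description[1], "first record")
  s <- parse_sequence(recs$sequence[2])
  expect_identical(s$mod_code[4], "m5C")
  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, out)
  expect_identical(read_fasta(out), recs)

  writeLines(c(">x", "ATGC"), path)
  expect_warning(recs <- read_fasta(path), "transliterating")
  expect_identical(recs$sequence, "AUGC")

  writeLines(c(">x", "AUGC", ">x", "AU"), path)
  expect_error(read_fasta(path), "duplicate")
  writeLines(c(">x", "AUBC"), path)
  expect_error(read_fasta(path), "illegal residue")
  writeLines(character(), path)
  expect_error(read_fasta(path), "empty")
})

test_that("decoy generation preserves length and composition", {
  recs <- data.frame(id = c("a", "b"), description = "",
                     sequence = c("AUGC", "GGAUCCAAUGGC"),
                     stringsAsFactors = FALSE)
  rev <- generate_decoys(recs, "reverse")
  expect_identical(rev$id, c("DECOY_a", "DECOY_b"))
  expect_identical(rev$sequence[1], "CGUA")
  shuf1 <- generate_decoys(recs, "shuffle", seed = 99)
  shuf2 <- generate_decoys(recs, "shuffle", seed = 99)
  expect_identical(shuf1, shuf2)            # deterministic given seed
  for (i in 1:2) {
    expect_identical(sort(strsplit(shuf1$sequence[i], "")[[1]]),
                     sort(strsplit(recs$sequence[i], "")[[1]]))
  }
  expect_error(generate_decoys(recs, "shuffle"), "seed")
  # modification tokens travel with their residue
  mrec <- data.frame(id = "m", description = "", sequence = "AU[m5C]Gp",
                     stringsAsFactors = FALSE)
  d <- generate_decoys(mrec, "reverse")
  expect_identical(d$sequence, "G[m5C]UAp")
})

test_that("RNase T1 digestion follows the cleavage rule oracle", {
  d0 <- digest_rnase_t1("CAUGGUCG", 0)
  expect_identical(vapply(d0, function(p) format(p$sequence), ""),
                   c("CAUGp", "Gp", "UCG"))
  expect_identical(vapply(d0, function(p) c(p$start, p$end), integer(2)),
                   matrix(c(1L, 4L, 5L, 5L, 6L, 8L), 2))
  d1 <- digest_rnase_t1("CAUGGUCG", 1)
  expect_setequal(vapply(d1, function(p) format(p$sequence), ""),
                  c("CAUGp", "CAUGGp", "Gp", "GUCG", "UCG"))
  expect_identical(format(digest_rnase_t1("AAA", 0)[[1]]$sequence), "AAA")
  # brute-force comparison on random sequences, several missed-cleavage levels
  set.seed(5)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "U"), sample(5:40, 1), replace = TRUE),
               collapse = "")
    for (mc in 0:2) {
      got <- vapply(digest_rnase_t1(s, mc), function(p)
        paste(p$sequence$residues, collapse = ""), "")
      expect_setequal(got, oracle_t1_fragments(s, mc))
    }
  }
})

test_that("digestion termini and reconstruction invariants hold", {
  parent <- parse_sequence("pCAUGGUCGA>p")
  prods <- digest_rnase_t1(parent, 0)
  expect_identical(prods[[1]]$sequence$five_prime, "phosphate")   # parent 5'
  expect_identical(prods[[1]]$sequence$three_prime, "phosphate")  # cleaved
  last <- prods[[length(prods)]]
  expect_identical(last$sequence$five_prime, "OH")
  expect_identical(last$sequence$three_prime, "cyclic_phosphate") # parent 3'
  # concatenating 0-missed products in order reproduces the parent
  set.seed(9)
  for (i in 1:10) {
    res <- sample(c("A", "C", "G", "U"), 30, replace = TRUE)
    prods <- digest_rnase_t1(na_sequence(res), 0)
    rebuilt <- unlist(lapply(prods, function(p) p$sequence$residues))
    expect_identical(rebuilt, res)
  }
  # modified G cleavage is configurable
  s <- "AU[mG?/b]CAG"
  expect_length(digest_rnase_t1(s, 0), 2L)
  expect_length(digest_rnase_t1(s, 0, cleave_modified_g = FALSE), 1L)
})

test_that("unspecific digestion enumerates substrings within bounds", {
  got <- vapply(digest_unspecific("AUGC", 3, 4), function(p)
    format(p$sequence), "")
  expect_setequal(got, c("AUG", "UGC", "AUGC"))
  expect_length(digest_unspecific("AUGC", 1, 4), 10L)
  expect_length(digest_unspecific("AUGC", 5, 8), 0L)
  expect_error(digest_unspecific("AUGC", 3, 2), "min_length")
  # internal substrings are 5'-OH/3'-OH; ends inherit parent termini
  prods <- digest_unspecific(parse_sequence("pAUGCA"), 2, 5)
  f <- vapply(prods, function(p) format(p$sequence), "")
  expect_true("pAU" %in% f)     # 5' end inherits phosphate
  expect_true("UG" %in% f)      # internal: no termini markers
})

test_that("modification enumeration matches the binomial-sum oracle", {
  p <- make_product("UCACAAAUCG")   # 3 C sites
  expect_length(enumerate_modifications(p, "m5C", max_mods = 3), 8L)
  expect_length(enumerate_modifications(p, "m5C", max_mods = 2), 7L)
  expect_length(enumerate_modifications(p, "m5C", max_mods = 0), 1L)
  expect_length(enumerate_modifications(p, character(), max_mods = 3), 1L)
  # brute-force count over the power set, random small products
  set.seed(13)
  for (i in 1:10) {
    res <- sample(c("A", "C", "G", "U"), sample(4:12, 1), replace = TRUE)
    p <- make_product(paste(res, collapse = ""))
    m <- sum(res == "C")
    for (mm in 0:3) {
      want <- sum(choose(m, 0:mm))
      expect_length(enumerate_modifications(p, "m5C", max_mods = mm), want)
    }
  }
})

test_that("either-placement enumeration doubles only discriminable sites", {
  # one internal C and one terminal C: internal gets base+sugar variants,
  # the 3'-terminal one (no a-B ion covers it) only one variant
  p <- make_product("ACAUC")
  cands <- enumerate_modifications(p, "mC?", max_mods = 1)
  keys <- vapply(cands, function(cand) format(cand$sequence), "")
  expect_setequal(keys, c("ACAUC", "A[mC?/b]AUC", "A[mC?/s]AUC", "ACAU[mC?/b]"))
  masses <- vapply(cands, function(cand) cand$neutral_mass, 0)
  expect_equal(masses[keys == "A[mC?/b]AUC"], masses[keys == "A[mC?/s]AUC"],
               tolerance = 1e-9)
})

test_that("candidate database dedupes by sequence and records locations", {
  recs <- data.frame(id = c("p1", "p2"), description = "",
                     sequence = c("GCAUGAAA", "AGCAUGUUU"),
                     stringsAsFactors = FALSE)
  cfg <- search_config(digestion = "rnase_t1", missed_cleavages = 0,
                       min_length = 3, max_mods = 0)
  db <- build_candidate_db(recs, cfg)
  i <- which(db$table$key == "CAUGp")
  expect_length(i, 1L)
  expect_setequal(db$table$locations[[i]], c("p1:2-5", "p2:3-6"))
  expect_false(is.unsorted(db$table$mass))
  # decoy count property
  recs2 <- rbind(recs, generate_decoys(recs, "reverse"))
  db2 <- build_candidate_db(recs2, cfg)
  expect_true(any(db2$table$is_decoy))
})
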