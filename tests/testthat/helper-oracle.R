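# Independent oracles used across tests. These deliberately avoid the
# package's chem_formula / fragment_mass_table code paths: masses are
# accumulated from explicit per-element atom counts.

oracle_masses <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196, P = 30.97376163, S = 31.97207100,
                   Na = 22.9897692809, K = 38.96370668)

# atom counts as plain named vectors
oracle_atoms <- list(
  A = c(C = 10, H = 13, N = 5, O = 4),
  C = c(C = 9, H = 13, N = 3, O = 5),
  G = c(C = 10, H = 13, N = 5, O = 5),
  U = c(C = 9, H = 12, N = 2, O = 6),
  baseA = c(C = 5, H = 5, N = 5),
  baseC = c(C = 4, H = 5, N = 3, O = 1),
  baseG = c(C = 5, H = 5, N = 5, O = 1),
  baseU = c(C = 4, H = 4, N = 2, O = 2),
  H2O = c(H = 2, O = 1),
  HPO3 = c(H = 1, P = 1, O = 3)
)

oracle_atom_mass <- function(atoms) sum(oracle_masses[names(atoms)] * atoms)

oracle_add <- function(a, b, k = 1) {
  for (el in names(b)) a[el] <- (if (is.na(a[el])) 0 else a[el]) + k * b[el]
  a
}

# neutral mass of an unmodified linear oligo (5'-OH / 3'-OH) by atom counting
oracle_oligo_mass <- function(residues) {
  n <- length(residues)
  atoms <- c(C = 0)
  for (r in residues) atoms <- oracle_add(atoms, oracle_atoms[[r]])
  atoms <- oracle_add(atoms, oracle_atoms$H2O, -(n - 1))
  atoms <- oracle_add(atoms, oracle_atoms$HPO3, n - 1)
  oracle_atom_mass(atoms)
}

# all nine fragment series of an unmodified 5'-OH/3'-OH oligo, computed from
# the structural composition of each fragment (prefix/suffix nucleosides plus
# the appropriate phosphate/water bookkeeping)
oracle_fragments <- function(residues) {
  n <- length(residues)
  out <- matrix(NA_real_, n - 1, 9,
                dimnames = list(NULL, c("a-B", "a", "b", "c", "d",
                                        "w", "x", "y", "z")))
  for (i in seq_len(n - 1)) {
    pre <- c(C = 0)
    for (r in residues[1:i]) pre <- oracle_add(pre, oracle_atoms[[r]])
    pre <- oracle_add(pre, oracle_atoms$H2O, -(i - 1))
    pre <- oracle_add(pre, oracle_atoms$HPO3, i - 1)
    c_at <- oracle_add(pre, oracle_atoms$HPO3)          # 3'-phosphate
    d_at <- oracle_add(c_at, oracle_atoms$H2O)
    b_at <- oracle_add(c_at, oracle_atoms$HPO3, -1)
    a_at <- oracle_add(b_at, oracle_atoms$H2O, -1)
    ab_at <- oracle_add(a_at, oracle_atoms[[paste0("base", residues[i])]], -1)
    suf <- c(C = 0)
    j <- n - i
    for (r in residues[(i + 1):n]) suf <- oracle_add(suf, oracle_atoms[[r]])
    suf <- oracle_add(suf, oracle_atoms$H2O, -(j - 1))
    suf <- oracle_add(suf, oracle_atoms$HPO3, j - 1)
    w_at <- oracle_add(suf, oracle_atoms$HPO3)          # 5'-phosphate
    x_at <- oracle_add(w_at, oracle_atoms$H2O, -1)
    y_at <- oracle_add(w_at, oracle_atoms$HPO3, -1)
    z_at <- oracle_add(y_at, oracle_atoms$H2O, -1)
    # 5' series are indexed by the prefix length i; 3' series by the
    # suffix length j (counted from the 3' end)
    out[i, c("a-B", "a", "b", "c", "d")] <-
      c(oracle_atom_mass(ab_at), oracle_atom_mass(a_at),
        oracle_atom_mass(b_at), oracle_atom_mass(c_at),
        oracle_atom_mass(d_at))
    out[j, c("w", "x", "y", "z")] <-
      c(oracle_atom_mass(w_at), oracle_atom_mass(x_at),
        oracle_atom_mass(y_at), oracle_atom_mass(z_at))
  }
  out
}

# brute-force RNase T1 digestion on a plain residue string
oracle_t1_fragments <- function(s, max_missed) {
  res <- strsplit(s, "")[[1]]
  cuts <- which(res == "G" & seq_along(res) < length(res))
  starts <- c(1L, cuts + 1L); ends <- c(cuts, length(res))
  out <- character()
  for (i in seq_along(starts)) {
    for (j in i:min(length(starts), i + max_missed)) {
      out <- c(out, paste(res[starts[i]:ends[j]], collapse = ""))
    }
  }
  out
}

# fixture sequences for oracle comparisons: a mix of compositions and
# lengths, including the mature let-7 miRNA sequence
FIXTURE_SEQS <- list(
  c("C", "G"),
  c("A", "U", "G", "C"),
  c("U", "C", "A", "C", "A", "A", "A", "U", "C", "G"),
  c("U", "A", "A", "C", "C", "C", "A", "A", "U", "G"),
  c("G", "G", "G", "G"),
  strsplit("UGAGGUAGUAGGUUGUAUAGUU", "")[[1]]
)

# a tiny digest product wrapper for enumerate_modifications tests
make_product <- function(seq_string) {
  s <- parse_sequence(seq_string)
  list(parent_id = "p", start = 1L, end = length(s$residues),
       missed_cleavages = 0L, sequence = s)
}
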