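#' In-silico RNase T1 digestion
#'
#' RNase T1 cleaves immediately 3' of guanosine, leaving a 3'-phosphate on
#' the upstream product and a 5'-hydroxyl on the downstream product. The
#' 5'-most / 3'-most products inherit the parent terminus on the uncut side.
#' Modified guanosines (origin base G) are cleaved by default, since modified
#' products ending in G are routinely observed; set `cleave_modified_g =
#' FALSE` to restrict cleavage to unmodified G.
#'
#' @param seq An `na_sequence` or a sequence string in bracket notation.
#' @param max_missed_cleavages Maximum number of internal (uncleaved) G
#'   sites per product.
#' @param min_length,max_length Product length bounds in nt.
#' @param cleave_modified_g Cleave after modified guanosines too?
#' @param parent_id Identifier recorded on the products.
#' @return A list of digest products; each has `parent_id`, `start`, `end`
#'   (1-based inclusive), `missed_cleavages` and `sequence` (an
#'   `na_sequence` with cleavage-determined termini).
#' @export
digest_rnase_t1 <- function(seq, max_missed_cleavages = 0L, min_length = 1L,
                            max_length = Inf, cleave_modified_g = TRUE,
                            parent_id = "parent") {
  if (is.character(seq)) seq <- parse_sequence(seq)
  stopifnot(max_missed_cleavages >= 0)
  n <- length(seq$residues)
  is_g <- seq$residues == "G"
  if (!cleave_modified_g) is_g <- is_g & is.na(seq$mod_code)
  cuts <- which(is_g[-n])            # cut after these positions
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  nseg <- length(starts)
  out <- list()
  for (i in seq_len(nseg)) {
    for (j in i:min(nseg, i + max_missed_cleavages)) {
      from <- starts[i]; to <- ends[j]
      len <- to - from + 1L
      if (len < min_length || len > max_length) next
      fp <- if (from == 1L) seq$five_prime else "OH"
      tp <- if (to == n) seq$three_prime else "phosphate"
      out[[length(out) + 1L]] <- list(
        parent_id = parent_id, start = from, end = to,
        missed_cleavages = j - i,
        sequence = subsequence(seq, from, to, fp, tp)
      )
    }
  }
  out
}

#' Unspecific in-silico cleavage
#'
#' Enumerates every contiguous subsequence within the length bounds, as
#' produced by incomplete solid-phase synthesis rather than an enzyme.
#' Internal substrings get 5'-OH/3'-OH termini; substrings reaching a parent
#' end inherit that parent terminus.
#'
#' @inheritParams digest_rnase_t1
#' @param min_length,max_length Substring length bounds (1 <= min <= max).
#' @return A list of digest products (see [digest_rnase_t1()]);
#'   `missed_cleavages` is 0 throughout.
#' @export
digest_unspecific <- function(seq, min_length = 5L, max_length = 40L,
                              parent_id = "parent") {
  if (is.character(seq)) seq <- parse_sequence(seq)
  if (min_length < 1 || min_length > max_length) {
    stop("require 1 <= min_length <= max_length")
  }
  n <- length(seq$residues)
  out <- list()
  for (from in seq_len(n)) {
    for (to in from:n) {
      len <- to - from + 1L
      if (len < min_length) next
      if (len > max_length) break
      fp <- if (from == 1L) seq$five_prime else "OH"
      tp <- if (to == n) seq$three_prime else "OH"
      out[[length(out) + 1L]] <- list(
        parent_id = parent_id, start = from, end = to, missed_cleavages = 0L,
        sequence = subsequence(seq, from, to, fp, tp)
      )
    }
  }
  out
}

#' Enumerate variably modified candidates of a digest product
#'
#' Fixed modifications are applied at every eligible residue. Variable
#' modifications are placed combinatorially: up to `max_mods` modified
#' positions per oligonucleotide, at most one modification per position.
#' For placement-ambiguous (`either`) modifications the base- and
#' sugar-located variants have identical precursor mass but different a-B
#' fragment masses, so both are emitted as distinct candidates whenever the
#' site is covered by an a-B ion (any position except the 3'-terminal one).
#'
#' @param product A digest product (see [digest_rnase_t1()]).
#' @param variable_mods Character vector of registry codes.
#' @param fixed_mods Character vector of registry codes.
#' @param max_mods Maximum number of variable modifications per candidate.
#' @return A list of candidates: each has the product's coordinates plus
#'   `sequence` (modified `na_sequence`), `neutral_mass` and `n_mods`.
#' @export
enumerate_modifications <- function(product, variable_mods = character(),
                                    fixed_mods = character(), max_mods = 0L) {
  stopifnot(max_mods >= 0)
  seq <- product$sequence
  n <- length(seq$residues)
  # fixed modifications first
  for (code in fixed_mods) {
    row <- modification_registry(code)
    targets <- strsplit(row$targets, ",", fixed = TRUE)[[1]]
    sites <- which(seq$residues %in% targets & is.na(seq$mod_code))
    if (!length(sites) && !any(seq$residues %in% targets)) {
      stop("fixed modification '", code, "' has no eligible residue in ",
           format(seq))
    }
    pl <- mod_resolved_placements(code)[1]
    seq$mod_code[sites] <- code
    seq$mod_placement[sites] <- pl
  }
  # site options: for each eligible (position, code) pair, list the resolved
  # placement variants
  options <- list()
  for (code in variable_mods) {
    row <- modification_registry(code)
    targets <- strsplit(row$targets, ",", fixed = TRUE)[[1]]
    sites <- which(seq$residues %in% targets & is.na(seq$mod_code))
    placements <- mod_resolved_placements(code)
    for (pos in sites) {
      pls <- if (length(placements) > 1 && pos == n) "base" else placements
      options[[length(options) + 1L]] <- list(pos = pos, code = code, pls = pls)
    }
  }
  results <- list()
  emit <- function(s, k) {
    cand <- product
    cand$sequence <- s
    cand$neutral_mass <- sequence_mass(s)
    cand$n_mods <- k
    results[[length(results) + 1L]] <<- cand
  }
  # depth-first combinatorial placement over option indices
  recurse <- function(next_i, used_pos, s, k) {
    emit(s, k)
    if (k == max_mods || next_i > length(options)) return()
    for (i in next_i:length(options)) {
      opt <- options[[i]]
      if (opt$pos %in% used_pos) next
      for (pl in opt$pls) {
        s2 <- s
        s2$mod_code[opt$pos] <- opt$code
        s2$mod_placement[opt$pos] <- pl
        recurse(i + 1L, c(used_pos, opt$pos), s2, k + 1L)
      }
    }
  }
  recurse(1L, integer(), seq, 0L)
  results
}
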