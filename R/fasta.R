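#' Read an RNA FASTA file
#'
#' Sequences are over A/C/G/U plus bracketed modification codes (e.g.
#' `AUG[m5C]C`). `T` is accepted and transliterated to `U` with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `description`, `sequence` (one
#'   row per record).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("FASTA parse error at line 1: expected '>' header")
  rec_idx <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(id))) {
    stop("FASTA parse error at line ", which(hdr)[!nzchar(id)][1], ": empty identifier")
  }
  if (anyDuplicated(id)) {
    stop("duplicate FASTA identifier(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seqs <- vapply(seq_along(headers), function(i) {
    paste(lines[rec_idx == i & !hdr], collapse = "")
  }, "")
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ", paste(id[!nzchar(seqs)], collapse = ", "))
  }
  # validate characters (outside brackets) and transliterate T -> U
  for (i in seq_along(seqs)) {
    stripped <- gsub("\\[[^]]*\\]", "", seqs[i])
    bad <- setdiff(strsplit(stripped, "")[[1]], c("A", "C", "G", "U", "T", "p", ">"))
    if (length(bad)) {
      line <- which(hdr)[i] + 1L
      stop("illegal residue character(s) ", paste(sQuote(bad), collapse = ", "),
           " in record '", id[i], "' (near line ", line, ")")
    }
  }
  if (any(grepl("T", gsub("\\[[^]]*\\]", "", seqs)))) {
    warning("'T' residues found; transliterating to 'U'")
    seqs <- vapply(seqs, function(s) {
      # only replace T outside brackets
      toks <- tokenize_residues(s)
      plain <- !startsWith(toks, "[")
      toks[plain] <- gsub("T", "U", toks[plain], fixed = TRUE)
      paste(toks, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  data.frame(id = id, description = description, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#' @param records Data frame with `id`, `description`, `sequence`.
#' @param path Output path. @param width Line width for sequence wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- records$description[i]
    writeLines(paste0(">", records$id[i], if (nzchar(desc)) paste0(" ", desc) else ""),
               con)
    # wrap on token boundaries so a bracketed modification never splits
    toks <- tokenize_residues(records$sequence[i])
    out <- character(); cur <- ""
    for (t in toks) {
      if (nzchar(cur) && nchar(cur) + nchar(t) > width) {
        out <- c(out, cur); cur <- ""
      }
      cur <- paste0(cur, t)
    }
    if (nzchar(cur)) out <- c(out, cur)
    writeLines(out, con)
  }
  invisible(path)
}

#' Generate decoy sequences
#'
#' One decoy per target, with identifier prefix `DECOY_`. `reverse` reverses
#' the residue order; `shuffle` permutes it (deterministically for a given
#' seed), preserving length and base composition. Bracketed modification
#' tokens travel with their residue.
#'
#' @param records Target records as returned by [read_fasta()].
#' @param method `"shuffle"` or `"reverse"`.
#' @param seed Integer seed; required for `"shuffle"`.
#' @return A data frame of decoy records.
#' @export
generate_decoys <- function(records, method = c("shuffle", "reverse"), seed = NULL) {
  method <- match.arg(method)
  if (method == "shuffle" && is.null(seed)) stop("shuffle decoys require a seed")
  toks_of <- function(s) {
    suffix3 <- ""
    if (endsWith(s, ">p")) { suffix3 <- ">p"; s <- substring(s, 1, nchar(s) - 2) }
    else if (endsWith(s, "p")) { suffix3 <- "p"; s <- substring(s, 1, nchar(s) - 1) }
    list(toks = tokenize_residues(s), suffix3 = suffix3)
  }
  one_decoy <- function(i) {
    tk <- toks_of(records$sequence[i])
    toks <- switch(method,
      reverse = rev(tk$toks),
      shuffle = tk$toks[sample.int(length(tk$toks))]
    )
    paste0(paste(toks, collapse = ""), tk$suffix3)
  }
  decoys <- if (method == "shuffle") {
    with_seed(seed, vapply(seq_len(nrow(records)), one_decoy, ""))
  } else {
    vapply(seq_len(nrow(records)), one_decoy, "")
  }
  data.frame(id = paste0("DECOY_", records$id),
             description = records$description,
             sequence = decoys, stringsAsFactors = FALSE)
}
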