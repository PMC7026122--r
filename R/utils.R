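## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Split a bracket-notation sequence body into residue tokens: each token is
## either a plain residue character or a complete "[...]" modification token.
tokenize_residues <- function(s) {
  regmatches(s, gregexpr("\\[[^]]*\\]|.", s))[[1]]
}

## ppm difference of `x` relative to `ref`
ppm_error <- function(x, ref) (x - ref) / ref * 1e6
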