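# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 9973) %% 2147483647L)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

other_strand <- function(strand) ifelse(strand == "+", "-", "+")

# Reverse complement of a DNA character string (vectorised).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)
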