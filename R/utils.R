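# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed when `seed` is non-NULL, otherwise use
# the current RNG stream. Generators call this so that an explicit seed
# gives bit-identical output while still composing inside a larger seeded
# simulation.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1) {
  assert_scalar_number(x, name, lower = lower)
  if (x != round(x)) abort(sprintf("`%s` must be an integer count", name))
  invisible(as.integer(x))
}

# Split DNA strings into an n x L character matrix (all strings length L).
seq_char_matrix <- function(x) {
  n <- length(x)
  L <- nchar(x[[1L]])
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = L, byrow = TRUE)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

DNA_BASES <- c("A", "C", "G", "T")
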