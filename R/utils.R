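# Internal helpers shared across the package.

# Classed conditions so callers (and the batch mapper) can dispatch on the
# failure mode rather than parse messages.
abort <- function(message, class) {
  stop(structure(
    class = c(class, "tol2_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single number or NULL", "invalid_argument")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Reduce possibly-negative 0-based positions into [0, L).
norm_pos <- function(p, L) ((p %% L) + L) %% L

# Circular substring: `len` bases starting at 0-based position `start0`,
# wrapping across the origin when needed.
subseq_circ <- function(sequence, start0, len) {
  L <- nchar(sequence)
  if (len == 0) {
    return("")
  }
  if (len > L) {
    abort("circular substring longer than the sequence", "invalid_argument")
  }
  s <- norm_pos(start0, L)
  if (s + len <= L) {
    substr(sequence, s + 1L, s + len)
  } else {
    paste0(substr(sequence, s + 1L, L), substr(sequence, 1L, s + len - L))
  }
}

# Vectorized reverse complement on plain character vectors.
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

# Table 1-style rounding: half values round away from zero, not to even.
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  grepl(pat, x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min),
          "invalid_argument")
  }
  as.integer(x)
}
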