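# Shared fixtures and independent oracles for the test suite.

# A small random plasmid with four disjoint features; cached per session.
toy_plasmid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_target_plasmid(2000, data.frame(
        name = c("hot", "f2", "f3", "f4"),
        fraction = c(0.25, 0.25, 0.25, 0.25),
        at = c(0.9, 0.5, 0.5, 0.5)), seed = 11)
    }
    cache
  }
})

# Brute-force TSD oracle: scan every k from max_len down.
brute_tsd_len <- function(left, right, max_len) {
  nl <- nchar(left)
  for (k in rev(seq_len(max_len))) {
    if (substr(left, nl - k + 1, nl) == substr(right, 1, k)) return(k)
  }
  0L
}

# Brute-force biased position sampler: explicit per-position weight
# vector (windowed AT fraction computed by direct circular indexing)
# and inverse-CDF draws.  Independent of position_weights()/filter().
brute_position_probs <- function(plasmid, beta_at, window) {
  b <- strsplit(plasmid$sequence, "", fixed = TRUE)[[1]]
  ind <- as.numeric(b %in% c("A", "T"))
  L <- length(ind)
  half <- (window - 1) / 2
  w <- vapply(seq_len(L), function(i) {
    idx <- ((i - 1 + (-half:half)) %% L) + 1
    exp(beta_at * mean(ind[idx]))
  }, numeric(1))
  w / sum(w)
}

brute_sample_positions <- function(probs, n) {
  cdf <- cumsum(probs)
  vapply(stats::runif(n), function(u) findInterval(u, cdf), numeric(1))
}

# Deterministic event table builder for mapping/hotspot tests.
manual_events <- function(position, orientation = "+",
                          experiment = "exp1", tsd_len = 8L,
                          plasmid = toy_plasmid()) {
  n <- length(position)
  orientation <- rep_len(orientation, n)
  experiment <- rep_len(experiment, n)
  tsd_len <- rep_len(tsd_len, n)
  data.frame(
    event_id = sprintf("ev%03d", seq_len(n)),
    position = as.integer(position),
    orientation = orientation,
    tsd_seq = vapply(seq_len(n), function(i) {
      subseq_circ_test(plasmid$sequence, position[i], tsd_len[i])
    }, character(1)),
    tsd_len = as.integer(tsd_len),
    canonical = tsd_len == 8L,
    experiment = experiment,
    stringsAsFactors = FALSE
  )
}

# Local circular substring (mirror of the package-internal helper, kept
# here so tests do not reach into unexported internals).
subseq_circ_test <- function(sequence, start0, len) {
  L <- nchar(sequence)
  if (len == 0) return("")
  s <- ((start0 %% L) + L) %% L
  if (s + len <= L) substr(sequence, s + 1, s + len)
  else paste0(substr(sequence, s + 1, L), substr(sequence, 1, s + len - L))
}

revcomp_test <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}
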