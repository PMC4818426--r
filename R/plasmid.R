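#' Construct a circular target plasmid
#'
#' The target plasmid is the coordinate frame for every downstream
#' operation: insertion positions, feature occupancy, hotspots and motif
#' extraction all refer to its circular coordinate system.  Coordinates
#' are 0-based and half-open, reduced modulo the plasmid length `L`;
#' the insertion position of an event is the index of the first base of
#' the target word that becomes duplicated on integration.
#'
#' @param name Plasmid identifier (single string).
#' @param sequence Circular DNA sequence over `A`, `C`, `G`, `T`
#'   (lowercase accepted, stored uppercase).
#' @param features Optional `data.frame` with columns `name`, `start`,
#'   `end` and optionally `strand` (`+`, `-` or `.`).  `start` is 0-based
#'   inclusive, `end` 0-based exclusive; `end <= start` denotes a feature
#'   wrapping across the origin.  Feature names must be unique.
#'
#' @return An object of class `target_plasmid`: a list with elements
#'   `name`, `sequence`, `length` and `features`.
#' @examples
#' p <- target_plasmid("toy", "ACGTACGTACGTACGTACGTACGTACGT",
#'   features = data.frame(name = c("a", "b"), start = c(0, 14),
#'                         end = c(14, 28)))
#' feature_lengths(p)
#' @export
target_plasmid <- function(name, sequence, features = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L || !is_dna(sequence)) {
    abort("plasmid sequence must be non-empty DNA over {A,C,G,T}",
          "invalid_argument")
  }
  L <- nchar(sequence)
  features <- normalize_features(features, L)
  structure(
    list(name = name, sequence = sequence, length = L, features = features),
    class = "target_plasmid"
  )
}

normalize_features <- function(features, L) {
  if (is.null(features) || nrow(as.data.frame(features)) == 0L) {
    return(data.frame(name = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(features))) {
    abort("features need columns name, start, end", "invalid_argument")
  }
  if (is.null(features$strand)) features$strand <- "."
  if (anyDuplicated(features$name)) {
    abort("feature names must be unique within a plasmid",
          "invalid_argument")
  }
  if (!all(features$strand %in% c("+", "-", "."))) {
    abort("feature strand must be one of '+', '-', '.'", "invalid_argument")
  }
  features$start <- as.integer(norm_pos(features$start, L))
  features$end <- as.integer(norm_pos(features$end, L))
  features[, c("name", "start", "end", "strand")]
}

#' @export
print.target_plasmid <- function(x, ...) {
  cat(sprintf("<target_plasmid> %s: %d bp circular, %d features\n",
              x$name, x$length, nrow(x$features)))
  if (nrow(x$features) > 0) {
    print(transform(x$features, length = feature_lengths(x)[name]))
  }
  invisible(x)
}

#' Feature lengths on a circular plasmid
#'
#' Length of each annotated feature in bp, `(end - start) mod L`, with 0
#' read as the full circle `L` (a feature may cover the whole plasmid).
#'
#' @param plasmid A [target_plasmid()].
#' @return Named integer vector of feature lengths.
#' @export
feature_lengths <- function(plasmid) {
  stopifnot(inherits(plasmid, "target_plasmid"))
  f <- plasmid$features
  if (nrow(f) == 0L) return(stats::setNames(integer(), character()))
  len <- (f$end - f$start) %% plasmid$length
  len[len == 0L] <- plasmid$length
  stats::setNames(as.integer(len), f$name)
}

#' Locate the feature containing each position
#'
#' Half-open convention: a position equal to a feature's `end` belongs to
#' the following feature, not this one.  Features wrapping the origin are
#' handled.
#'
#' @param plasmid A [target_plasmid()].
#' @param position Vector of 0-based positions (reduced mod `L`).
#' @return Character vector of feature names, `NA` where the position
#'   falls outside every annotated feature.
#' @export
feature_at <- function(plasmid, position) {
  stopifnot(inherits(plasmid, "target_plasmid"))
  pos <- norm_pos(position, plasmid$length)
  f <- plasmid$features
  out <- rep(NA_character_, length(pos))
  if (nrow(f) == 0L) return(out)
  lens <- feature_lengths(plasmid)
  for (i in seq_len(nrow(f))) {
    s <- f$start[i]; e <- f$end[i]
    hit <- if (lens[[i]] == plasmid$length) {
      rep(TRUE, length(pos))
    } else if (s < e) {
      pos >= s & pos < e
    } else {
      pos >= s | pos < e
    }
    out[is.na(out) & hit] <- f$name[i]
  }
  out
}

#' AT fraction of DNA strings
#'
#' @param x Character vector of DNA strings.
#' @return Numeric vector: fraction of `A`/`T` bases in each string
#'   (`NaN` for empty strings).
#' @export
at_fraction <- function(x) {
  x <- toupper(x)
  vapply(x, function(s) {
    n <- nchar(s)
    if (n == 0L) return(NaN)
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    mean(b == "A" | b == "T")
  }, numeric(1), USE.NAMES = FALSE)
}

#' Windowed local AT fraction around every plasmid position
#'
#' Circular centered moving average of the A/T indicator; this is the
#' covariate the insertion bias model acts on.
#'
#' @param plasmid A [target_plasmid()].
#' @param window Odd window width in bp (>= 1).
#' @return Numeric vector of length `L`; element `i` is the AT fraction
#'   of the window centered on 0-based position `i - 1`.
#' @export
local_at_fraction <- function(plasmid, window = 51) {
  stopifnot(inherits(plasmid, "target_plasmid"))
  window <- check_count(window, "window", min = 1)
  if (window %% 2L == 0L) {
    abort("`window` must be odd", "invalid_argument")
  }
  if (window > plasmid$length) {
    abort("`window` larger than the plasmid", "invalid_argument")
  }
  b <- strsplit(plasmid$sequence, "", fixed = TRUE)[[1]]
  ind <- as.numeric(b == "A" | b == "T")
  as.numeric(stats::filter(ind, rep(1 / window, window),
                           method = "convolution", sides = 2,
                           circular = TRUE))
}

#' Generate a synthetic target plasmid with AT-controlled features
#'
#' Builds a circular plasmid whose features tile the sequence in the
#' order given, each with a prescribed fraction of the total length and a
#' target AT content.  Base composition is exact up to rounding: each
#' feature receives `round(at * len)` A/T bases placed uniformly at
#' random, so realized AT content differs from the target by at most
#' `0.5 / len`.  Any length not covered by the feature fractions becomes
#' an unannotated tail at AT content `unannotated_at`.
#'
#' @param length Plasmid length in bp (>= 100).
#' @param feature_spec `data.frame` (or list of 3-element vectors) with
#'   columns `name`, `fraction` (of total length, summing to <= 1) and
#'   `at` (target AT fraction in `[0, 1]`).
#' @param seed Integer seed for reproducible generation, or `NULL`.
#' @param name Plasmid identifier.
#' @param unannotated_at AT fraction of the uncovered remainder.
#' @return A [target_plasmid()].
#' @examples
#' p <- make_target_plasmid(4000, data.frame(
#'   name = c("sv40_polyA", "ampR", "ori", "backbone"),
#'   fraction = c(0.10, 0.25, 0.15, 0.50),
#'   at = c(0.64, 0.50, 0.50, 0.50)), seed = 7)
#' at_fraction(subseq_plasmid(p, "sv40_polyA"))
#' @export
make_target_plasmid <- function(length, feature_spec, seed = NULL,
                                name = "synthetic_plasmid",
                                unannotated_at = 0.5) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 100) {
    abort("`length` must be a single integer >= 100", "invalid_argument")
  }
  length <- as.integer(length)
  spec <- as.data.frame(do.call(rbind, lapply(
    if (is.data.frame(feature_spec)) split(feature_spec, seq_len(nrow(feature_spec)))
    else feature_spec,
    function(row) {
      row <- as.list(row)
      names(row) <- c("name", "fraction", "at")[seq_along(row)]
      data.frame(name = as.character(row$name),
                 fraction = as.numeric(row$fraction),
                 at = as.numeric(row$at), stringsAsFactors = FALSE)
    })), stringsAsFactors = FALSE)
  if (any(spec$fraction <= 0) || sum(spec$fraction) > 1 + 1e-9) {
    abort("feature fractions must be positive and sum to <= 1",
          "invalid_argument")
  }
  if (any(spec$at < 0 | spec$at > 1)) {
    abort("target AT fractions must lie in [0, 1]", "invalid_argument")
  }
  bounds <- round(cumsum(c(0, spec$fraction)) * length)
  sizes <- as.integer(diff(bounds))
  if (any(sizes < 1L)) {
    abort("every feature must round to at least 1 bp", "invalid_argument")
  }
  with_seed(seed, {
    segs <- mapply(random_dna, sizes, spec$at, SIMPLIFY = TRUE)
    tail_len <- length - sum(sizes)
    tail_seq <- if (tail_len > 0) random_dna(tail_len, unannotated_at) else ""
    sequence <- paste0(paste(segs, collapse = ""), tail_seq)
    features <- data.frame(
      name = spec$name,
      start = as.integer(bounds[-base::length(bounds)]),
      end = as.integer(bounds[-1]) %% length,
      strand = ".",
      stringsAsFactors = FALSE
    )
    target_plasmid(name, sequence, features)
  })
}

# Random DNA of length `len` with exactly round(at * len) A/T bases.
random_dna <- function(len, at) {
  n_at <- round(at * len)
  is_at <- rep(FALSE, len)
  if (n_at > 0) is_at[sample.int(len, n_at)] <- TRUE
  base <- character(len)
  base[is_at] <- sample(c("A", "T"), n_at, replace = TRUE)
  base[!is_at] <- sample(c("C", "G"), len - n_at, replace = TRUE)
  paste(base, collapse = "")
}

#' Extract a feature's sequence from a plasmid
#'
#' @param plasmid A [target_plasmid()].
#' @param feature Feature name.
#' @return The feature's DNA sequence (wrapping the origin if needed).
#' @export
subseq_plasmid <- function(plasmid, feature) {
  stopifnot(inherits(plasmid, "target_plasmid"))
  f <- plasmid$features
  i <- match(feature, f$name)
  if (is.na(i)) abort("no such feature", "invalid_argument")
  subseq_circ(plasmid$sequence, f$start[i], feature_lengths(plasmid)[[i]])
}
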