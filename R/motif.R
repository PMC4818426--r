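#' Build the integration-site consensus motif
#'
#' For every event with a canonical 8-bp duplication, extracts the
#' 14-mer covering 3 bp upstream, the 8-bp duplicated word and 3 bp
#' downstream, read on the insertion's reported strand (minus-strand
#' events contribute the reverse complement of the plus-strand window,
#' so the motif is transposon-centric).  Base counts are accumulated
#' into a 4 x 14 matrix and collapsed to an IUPAC consensus per column:
#' a single base when its frequency reaches `strong_threshold`; a
#' two-base IUPAC code when the top two bases jointly reach
#' `strong_threshold` and each reaches `majority_threshold / 2`
#' (0.25 at the default); otherwise `N`.
#'
#' Events lacking a canonical TSD are skipped with a warning giving the
#' skipped count.
#'
#' @param events Event `data.frame` (columns `position`, `orientation`,
#'   `tsd_len`, `canonical`).
#' @param plasmid A [target_plasmid()].
#' @param majority_threshold Two-base component floor control
#'   (default 0.5).
#' @param strong_threshold Single-base/joint frequency threshold
#'   (default 0.8).
#' @return Object of class `insertion_motif`: list with `counts`
#'   (4 x 14, rows `A`, `C`, `G`, `T`; every column sums to `n_sites`),
#'   `consensus` (IUPAC string, length 14), `n_sites`.
#' @export
build_motif <- function(events, plasmid, majority_threshold = 0.5,
                        strong_threshold = 0.8) {
  stopifnot(inherits(plasmid, "target_plasmid"))
  keep <- !is.na(events$canonical) & events$canonical & events$tsd_len == 8L
  n_skip <- nrow(events) - sum(keep)
  if (n_skip > 0L) {
    warning(sprintf("build_motif: skipped %d event(s) without a canonical 8-bp TSD",
                    n_skip))
  }
  ev <- events[keep, , drop = FALSE]
  counts <- matrix(0L, nrow = 4L, ncol = 14L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nrow(ev))) {
    win <- subseq_circ(plasmid$sequence, ev$position[i] - 3L, 14L)
    if (ev$orientation[i] == "-") win <- revcomp(win)
    b <- strsplit(win, "", fixed = TRUE)[[1]]
    for (j in seq_len(14L)) {
      counts[b[j], j] <- counts[b[j], j] + 1L
    }
  }
  structure(list(
    counts = counts,
    consensus = consensus_iupac(counts, majority_threshold,
                                strong_threshold),
    n_sites = nrow(ev)
  ), class = "insertion_motif")
}

# Collapse a 4 x w count matrix to an IUPAC consensus string.
consensus_iupac <- function(counts, majority_threshold = 0.5,
                            strong_threshold = 0.8) {
  pair_codes <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y",
                  GT = "K")
  n <- colSums(counts)
  vapply(seq_len(ncol(counts)), function(j) {
    if (n[j] == 0L) return("N")
    freq <- sort(counts[, j] / n[j], decreasing = TRUE)
    if (freq[1] >= strong_threshold) return(names(freq)[1])
    if (freq[1] + freq[2] >= strong_threshold &&
        freq[2] >= majority_threshold / 2) {
      return(pair_codes[[paste(sort(names(freq)[1:2]), collapse = "")]])
    }
    "N"
  }, character(1)) |> paste(collapse = "")
}

#' @export
print.insertion_motif <- function(x, ...) {
  cat(sprintf("<insertion_motif> n_sites=%d consensus=%s\n",
              x$n_sites, x$consensus))
  invisible(x)
}

#' Reference Tol2 integration consensus
#'
#' The weak AT-rich integration consensus reported for Tol2,
#' `TNA(C/G)TTATAA(G/C)TNA`, as a 14-character IUPAC string (`S` = C or
#' G); positions 4-11 are the 8-bp insertion site.
#'
#' @return `"TNASTTATAASTNA"`.
#' @export
tol2_reference_consensus <- function() "TNASTTATAASTNA"

#' Test compatibility of two IUPAC consensus strings
#'
#' `x` is compatible with `reference` when, at every position, the base
#' set denoted by `x`'s code is a subset of the set denoted by the
#' reference code (so a sharper consensus is compatible with a looser
#' one).
#'
#' @param x Consensus to test.
#' @param reference Reference consensus (default
#'   [tol2_reference_consensus()]).
#' @return `TRUE`/`FALSE`.
#' @export
consensus_compatible <- function(x, reference = tol2_reference_consensus()) {
  if (nchar(x) != nchar(reference)) return(FALSE)
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
               S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  xs <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  rs <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  all(vapply(seq_along(xs), function(i) {
    all(sets[[xs[i]]] %in% sets[[rs[i]]])
  }, logical(1)))
}

#' AT enrichment at insertion sites
#'
#' Compares the local AT fraction around insertion positions with the
#' plasmid background.  Site AT is the mean windowed AT fraction over
#' windows centered on the insertion positions; background is the
#' whole-plasmid AT fraction; per-feature values come from the feature
#' sequences alone.
#'
#' @param events Event `data.frame` with a `position` column.
#' @param plasmid A [target_plasmid()].
#' @param window Odd window width in bp (default 51).
#' @return List with `site_at`, `background_at`, `feature_at` (named
#'   numeric vector), `window`, `n_events`.
#' @export
at_enrichment <- function(events, plasmid, window = 51) {
  stopifnot(inherits(plasmid, "target_plasmid"))
  local_at <- local_at_fraction(plasmid, window)
  site_at <- if (nrow(events) > 0L) {
    mean(local_at[norm_pos(events$position, plasmid$length) + 1L])
  } else {
    NaN
  }
  feats <- plasmid$features$name
  feat_at <- stats::setNames(
    vapply(feats, function(f) at_fraction(subseq_plasmid(plasmid, f)),
           numeric(1)),
    feats)
  list(site_at = site_at,
       background_at = at_fraction(plasmid$sequence),
       feature_at = feat_at,
       window = as.integer(window),
       n_events = nrow(events))
}
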