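#' Detect a target-site duplication between two junction flanks
#'
#' hAT transposition duplicates an 8-bp target word so that, on the
#' plasmid plus strand, the upstream (left) flank ends with the word and
#' the downstream (right) flank begins with it.  `detect_tsd` returns
#' the longest `k <= max_len` such that the length-`k` suffix of
#' `left_flank` equals the length-`k` prefix of `right_flank`; `k = 0`
#' (a blunt joint, no duplication) is allowed.  The longest such `k` is
#' unique, so there are no ties.  The canonical hAT signature is
#' `k = 8` with identical copies.
#'
#' `max_len` defaults to 12 rather than 8 so over-long duplications are
#' observed rather than clipped: "canonical" is a classification of the
#' call, not an assumption of the scan.
#'
#' @param left_flank,right_flank Plus-strand flank sequences, each at
#'   least `max_len` bases long (lowercase accepted).
#' @param max_len Maximum duplication length searched (default 12).
#' @return An object of class `tsd_call`: list with `tsd_seq`,
#'   `tsd_len`, `canonical` (`tsd_len == 8`).
#' @examples
#' detect_tsd("aaatatttaccaagcaac", "caagcaacacgttcagtg")
#' @export
detect_tsd <- function(left_flank, right_flank, max_len = 12) {
  max_len <- check_count(max_len, "max_len", min = 0)
  left_flank <- toupper(left_flank)
  right_flank <- toupper(right_flank)
  if (nchar(left_flank) < max_len || nchar(right_flank) < max_len) {
    abort("both flanks must be at least `max_len` bases long",
          "invalid_argument")
  }
  nl <- nchar(left_flank)
  for (k in rev(seq_len(max_len))) {
    if (substr(left_flank, nl - k + 1L, nl) == substr(right_flank, 1L, k)) {
      return(new_tsd_call(substr(right_flank, 1L, k), k))
    }
  }
  new_tsd_call("", 0L)
}

new_tsd_call <- function(tsd_seq, tsd_len) {
  structure(list(tsd_seq = tsd_seq, tsd_len = as.integer(tsd_len),
                 canonical = tsd_len == 8L),
            class = "tsd_call")
}

#' @export
print.tsd_call <- function(x, ...) {
  cat(sprintf("<tsd_call> len=%d%s %s\n", x$tsd_len,
              if (x$canonical) " (canonical)" else "",
              if (x$tsd_len > 0) x$tsd_seq else "(blunt)"))
  invisible(x)
}

#' Summarize canonical-TSD rate over a set of calls
#'
#' @param calls A list of [detect_tsd()] calls, or a `data.frame` with
#'   columns `tsd_len` and `canonical` (e.g. an event table).
#' @return List with `fraction_canonical` (canonical count / total),
#'   `n` and `counts_by_length` (named integer vector over observed
#'   duplication lengths).
#' @examples
#' calls <- list(detect_tsd("AAATATTTACCAAGCAAC", "CAAGCAACACGTTCAGTG"),
#'               detect_tsd("AAAAAAAAAAAA", "CCCCCCCCCCCC"))
#' tsd_rate(calls)$fraction_canonical
#' @export
tsd_rate <- function(calls) {
  if (is.data.frame(calls)) {
    if (nrow(calls) == 0L) abort("no TSD calls supplied", "empty_input")
    lens <- calls$tsd_len
    canon <- calls$canonical
  } else {
    if (length(calls) == 0L) abort("no TSD calls supplied", "empty_input")
    lens <- vapply(calls, function(x) x$tsd_len, integer(1))
    canon <- vapply(calls, function(x) x$canonical, logical(1))
  }
  tab <- table(factor(lens, levels = 0:max(c(lens, 8L))))
  list(
    fraction_canonical = mean(canon),
    n = length(lens),
    counts_by_length = stats::setNames(as.integer(tab), names(tab))
  )
}
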