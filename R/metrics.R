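#' Colony counts from an in vitro integration assay
#'
#' After transforming the reaction products, the library is plated on
#' kanamycin (integration products) and ampicillin (all target
#' plasmids).  `*_plated_fraction` is the fraction of the transformation
#' plated on each selection, so counts can be scaled to totals.
#'
#' @param kan_colonies,amp_colonies Colony counts (>= 0).
#' @param kan_plated_fraction,amp_plated_fraction Fractions in `(0, 1]`.
#' @return Object of class `colony_counts`.
#' @export
colony_counts <- function(kan_colonies, amp_colonies,
                          kan_plated_fraction = 1,
                          amp_plated_fraction = 1) {
  kan_colonies <- check_count(kan_colonies, "kan_colonies")
  amp_colonies <- check_count(amp_colonies, "amp_colonies")
  for (f in c(kan_plated_fraction, amp_plated_fraction)) {
    if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1) {
      abort("plated fractions must lie in (0, 1]", "invalid_argument")
    }
  }
  structure(list(kan_colonies = kan_colonies,
                 amp_colonies = amp_colonies,
                 kan_plated_fraction = kan_plated_fraction,
                 amp_plated_fraction = amp_plated_fraction),
            class = "colony_counts")
}

#' Integration ratio of an in vitro assay
#'
#' The Kan+/Amp+ colony ratio, each count scaled by its plated
#' fraction: `(kan / kan_plated_fraction) / (amp / amp_plated_fraction)`.
#' This is the standard indicator of integration activity (the fraction
#' of target plasmids carrying an insertion).  Invariant to scaling
#' both plated fractions by a common factor.
#'
#' @param counts A [colony_counts()].
#' @return The integration ratio (fraction; multiply by 100 for
#'   percent).
#' @examples
#' integration_ratio(colony_counts(40, 5000))  # 0.008 = 0.8%
#' @export
integration_ratio <- function(counts) {
  stopifnot(inherits(counts, "colony_counts"))
  amp_total <- counts$amp_colonies / counts$amp_plated_fraction
  if (amp_total <= 0) {
    abort("no Amp+ colonies: integration ratio undefined",
          "undefined_ratio")
  }
  (counts$kan_colonies / counts$kan_plated_fraction) / amp_total
}

#' Germline trapping frequency
#'
#' Percentage of founder (F0) fish producing transgene-positive
#' offspring, reported to the nearest integer percent (half values round
#' up), matching the usual founder-table formatting.
#'
#' @param positive_founders Founders with positive offspring.
#' @param total_founders Founders screened (>= 1).
#' @return Integer percentage.
#' @examples
#' germline_frequency(13, 20)  # 65
#' germline_frequency(9, 10)   # 90
#' @export
germline_frequency <- function(positive_founders, total_founders) {
  positive_founders <- check_count(positive_founders, "positive_founders")
  total_founders <- check_count(total_founders, "total_founders")
  if (total_founders < 1L) {
    abort("no founders screened", "empty_input")
  }
  if (positive_founders > total_founders) {
    abort("positive founders exceed total founders", "invalid_argument")
  }
  round_half_up(100 * positive_founders / total_founders)
}

#' Germline mosaicism
#'
#' Per-founder mosaicism is the percentage of transgene-positive F1
#' offspring from a founder outcross; the category-level value is the
#' unweighted mean over founders, rounded half-up to the nearest integer
#' percent.  Lower mosaicism indicates earlier integration during
#' embryogenesis.
#'
#' @param f1_positive,f1_total Per-founder F1 counts (parallel vectors;
#'   every `f1_total >= 1`).
#' @return List with `per_founder` (numeric percentages) and `average`
#'   (integer percent).
#' @examples
#' mosaicism(c(20, 34), c(100, 100))$average  # 27
#' @export
mosaicism <- function(f1_positive, f1_total) {
  if (length(f1_positive) != length(f1_total) ||
      length(f1_total) == 0L) {
    abort("need matching, non-empty per-founder F1 counts", "empty_input")
  }
  if (any(f1_total < 1)) abort("every founder needs f1_total >= 1",
                               "empty_input")
  if (any(f1_positive < 0) || any(f1_positive > f1_total)) {
    abort("f1_positive must lie in [0, f1_total]", "invalid_argument")
  }
  per <- 100 * f1_positive / f1_total
  list(per_founder = per, average = round_half_up(mean(per)))
}

#' Summarize a founder table
#'
#' Convenience wrapper applying [germline_frequency()] row-wise to a
#' founder table (one row per somatic category / transposase form).
#'
#' @param founders `data.frame` with columns `category`, `form`,
#'   `positive_founders`, `total_founders`.
#' @return The input with an added `germline_frequency` column
#'   (integer percent).
#' @export
founder_summary <- function(founders) {
  stopifnot(is.data.frame(founders),
            all(c("positive_founders", "total_founders") %in%
                  names(founders)))
  founders$germline_frequency <- vapply(seq_len(nrow(founders)),
    function(i) germline_frequency(founders$positive_founders[i],
                                   founders$total_founders[i]),
    numeric(1))
  founders
}
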