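#' Build an occupancy table
#'
#' Small container for per-feature insertion counts: the input of the
#' Monte Carlo bias test.
#'
#' @param feature Feature names.
#' @param length Feature lengths in bp (>= 1).
#' @param observed Observed insertion counts (>= 0).
#' @return `data.frame` of class `occupancy_table` with attribute
#'   `n_total = sum(observed)`.
#' @export
occupancy_table <- function(feature, length, observed) {
  if (base::length(feature) == 0L) {
    abort("occupancy table needs at least one feature", "empty_input")
  }
  if (any(length < 1) || any(observed < 0)) {
    abort("feature lengths must be >= 1 and counts >= 0",
          "invalid_argument")
  }
  if (anyDuplicated(feature)) {
    abort("feature names must be unique", "invalid_argument")
  }
  out <- data.frame(feature = as.character(feature),
                    length = as.integer(length),
                    observed = as.integer(observed),
                    stringsAsFactors = FALSE)
  attr(out, "n_total") <- sum(out$observed)
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Count insertions per annotated feature
#'
#' Assigns each event to the feature containing its position (half-open
#' intervals: a position equal to a feature's `end` belongs to the next
#' feature).  Events outside every feature are counted under a synthetic
#' `unannotated` feature whose length is the uncovered plasmid length,
#' so the multinomial probability model of the bias test is proper.
#' Overlapping features are rejected: the test's length-proportional
#' probabilities require a disjoint feature set.
#'
#' @param events Event `data.frame` with a `position` column.
#' @param plasmid A [target_plasmid()] with at least one feature.
#' @return An [occupancy_table()].
#' @export
feature_occupancy <- function(events, plasmid) {
  stopifnot(inherits(plasmid, "target_plasmid"))
  f <- plasmid$features
  if (nrow(f) == 0L) {
    abort("plasmid has no annotated features", "invalid_argument")
  }
  lens <- feature_lengths(plasmid)
  if (sum(lens) > plasmid$length || features_overlap(plasmid)) {
    abort("features overlap: occupancy model requires disjoint features",
          "ambiguous_annotation")
  }
  hits <- feature_at(plasmid, events$position)
  counts <- table(factor(hits, levels = f$name))
  out_feature <- f$name
  out_length <- as.integer(lens)
  out_obs <- as.integer(counts)
  uncovered <- plasmid$length - sum(lens)
  if (uncovered > 0L) {
    out_feature <- c(out_feature, "unannotated")
    out_length <- c(out_length, uncovered)
    out_obs <- c(out_obs, sum(is.na(hits)))
  }
  occupancy_table(out_feature, out_length, out_obs)
}

# TRUE if any two features share a position (circular intervals).
features_overlap <- function(plasmid) {
  f <- plasmid$features
  if (nrow(f) < 2L) return(FALSE)
  L <- plasmid$length
  lens <- feature_lengths(plasmid)
  pieces <- do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
    s <- f$start[i]; e <- s + lens[[i]]
    if (e <= L) cbind(s, e) else rbind(cbind(s, L), cbind(0L, e - L))
  }))
  pieces <- pieces[order(pieces[, 1]), , drop = FALSE]
  any(pieces[-1, 1] < pieces[-nrow(pieces), 2])
}

#' Monte Carlo test of feature-occupancy bias
#'
#' Simulates the length-proportional null for the observed insertion
#' total: `n_sims` multinomial draws of `n_total` counts with
#' per-feature probability `length_i / sum(length)`.  For each feature
#' the empirical one-sided p-values record how often simulated counts
#' reach or exceed (`p_greater`) or fall at or below (`p_less`) the
#' observed count, with the add-one correction
#' `p = (1 + #extreme) / (1 + n_sims)` so reported p-values are never
#' zero.  Both one-sided values are reported rather than a folded
#' two-sided p.
#'
#' @param occupancy An [occupancy_table()].
#' @param n_sims Number of simulations (default 10000).
#' @param seed Integer seed or `NULL`.
#' @return `data.frame` of class `mc_bias_test` with columns `feature`,
#'   `length`, `observed`, `expected`, `p_greater`, `p_less`;
#'   attributes `n_sims`, `n_total`, `seed`.
#' @examples
#' occ <- occupancy_table(c("a", "b"), c(500, 500), c(5, 0))
#' monte_carlo_bias_test(occ, n_sims = 1000, seed = 1)
#' @export
monte_carlo_bias_test <- function(occupancy, n_sims = 10000, seed = NULL) {
  stopifnot(inherits(occupancy, "occupancy_table"))
  n_sims <- check_count(n_sims, "n_sims", min = 1)
  n_total <- sum(occupancy$observed)
  if (n_total < 1L) {
    abort("occupancy table has no observed insertions", "empty_input")
  }
  p <- occupancy$length / sum(occupancy$length)
  sims <- with_seed(seed, stats::rmultinom(n_sims, n_total, p))
  p_greater <- (1 + rowSums(sims >= occupancy$observed)) / (1 + n_sims)
  p_less <- (1 + rowSums(sims <= occupancy$observed)) / (1 + n_sims)
  out <- data.frame(feature = occupancy$feature,
                    length = occupancy$length,
                    observed = occupancy$observed,
                    expected = n_total * p,
                    p_greater = p_greater,
                    p_less = p_less,
                    stringsAsFactors = FALSE)
  attr(out, "n_sims") <- n_sims
  attr(out, "n_total") <- n_total
  attr(out, "seed") <- seed
  class(out) <- c("mc_bias_test", "data.frame")
  out
}

#' Exact multinomial tail probability by enumeration
#'
#' Independent oracle for [monte_carlo_bias_test()] on small instances:
#' enumerates every count vector of the length-proportional multinomial
#' and sums the probability of those where the focal feature's count
#' reaches the observed value, i.e. the exact value the Monte Carlo
#' `p_greater` estimates (without the add-one correction).
#'
#' @param occupancy An [occupancy_table()] with `n_total <= 12` and at
#'   most 4 features (enumeration stays feasible).
#' @param feature Focal feature name.
#' @return Exact `P(count_feature >= observed)` under the null.
#' @examples
#' exact_multinomial_tail(
#'   occupancy_table(c("a", "b"), c(500, 500), c(5, 0)), "a")  # 1/32
#' @export
exact_multinomial_tail <- function(occupancy, feature) {
  stopifnot(inherits(occupancy, "occupancy_table"))
  n <- sum(occupancy$observed)
  f <- nrow(occupancy)
  if (n > 12L || f > 4L) {
    abort("instance too large for exact enumeration (n_total <= 12, <= 4 features)",
          "unsupported_size")
  }
  i <- match(feature, occupancy$feature)
  if (is.na(i)) abort("no such feature in occupancy table",
                      "invalid_argument")
  p <- occupancy$length / sum(occupancy$length)
  obs <- occupancy$observed[i]
  total <- 0
  for (vec in enumerate_compositions(n, f)) {
    if (vec[i] >= obs) {
      total <- total + stats::dmultinom(vec, prob = p)
    }
  }
  total
}

# All vectors of f non-negative integers summing to n.
enumerate_compositions <- function(n, f) {
  if (f == 1L) return(list(n))
  out <- list()
  for (k in 0:n) {
    for (rest in enumerate_compositions(n - k, f - 1L)) {
      out[[length(out) + 1L]] <- c(k, rest)
    }
  }
  out
}
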