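#' Insertion bias model
#'
#' Generative model for where a transposon integrates on the target
#' plasmid.  Per-position sampling weights are
#' `w(p) = exp(beta_at * ATfrac(window centered on p))`, optionally
#' multiplied by a positional motif term, then normalized to sum to 1.
#' With `beta_at = 0` and no motif weights the model is uniform over all
#' positions -- the null the occupancy Monte Carlo test simulates.
#'
#' The duplication-fidelity parameter gives the probability that an
#' integration carries the canonical 8-bp target-site duplication; with
#' probability `1 - tsd_fidelity` the event instead carries an exact
#' duplication of aberrant length drawn uniformly from {0..7, 9, 10}.
#' The default fidelity of 0.86 matches the canonical-TSD rate observed
#' for in vitro Tol2 integration.
#'
#' @param beta_at Log-weight per unit AT fraction (>= 0).
#' @param window Odd window width in bp for the local AT fraction.
#' @param motif_weights Optional 4 x 14 matrix of per-position log-weights
#'   (rows `A`, `C`, `G`, `T`; columns 3 bp upstream + 8-bp site + 3 bp
#'   downstream) added to the log-weight of each candidate position.
#' @param tsd_fidelity Probability in `[0, 1]` of a canonical 8-bp TSD.
#' @return An object of class `bias_model`.
#' @export
bias_model <- function(beta_at = 8, window = 51, motif_weights = NULL,
                       tsd_fidelity = 0.86) {
  if (!is.numeric(beta_at) || length(beta_at) != 1L || beta_at < 0) {
    abort("`beta_at` must be a single number >= 0", "invalid_argument")
  }
  window <- check_count(window, "window", min = 1)
  if (window %% 2L == 0L) abort("`window` must be odd", "invalid_argument")
  if (!is.numeric(tsd_fidelity) || length(tsd_fidelity) != 1L ||
      tsd_fidelity < 0 || tsd_fidelity > 1) {
    abort("`tsd_fidelity` must lie in [0, 1]", "invalid_argument")
  }
  if (!is.null(motif_weights)) {
    if (!is.matrix(motif_weights) || !identical(dim(motif_weights), c(4L, 14L))) {
      abort("`motif_weights` must be a 4 x 14 matrix", "invalid_argument")
    }
    if (is.null(rownames(motif_weights))) {
      rownames(motif_weights) <- c("A", "C", "G", "T")
    }
  }
  structure(list(beta_at = beta_at, window = as.integer(window),
                 motif_weights = motif_weights,
                 tsd_fidelity = tsd_fidelity),
            class = "bias_model")
}

#' Per-position insertion sampling weights
#'
#' @param plasmid A [target_plasmid()].
#' @param bias A [bias_model()].
#' @return Numeric vector of length `L`, positive, finite, summing to 1;
#'   element `i` is the probability that a simulated insertion lands at
#'   0-based position `i - 1`.
#' @export
position_weights <- function(plasmid, bias = bias_model()) {
  stopifnot(inherits(plasmid, "target_plasmid"),
            inherits(bias, "bias_model"))
  logw <- bias$beta_at * local_at_fraction(plasmid, bias$window)
  if (!is.null(bias$motif_weights)) {
    b <- strsplit(plasmid$sequence, "", fixed = TRUE)[[1]]
    L <- plasmid$length
    for (j in seq_len(14L)) {
      # column j covers offset j - 4 from the insertion position
      idx <- ((seq_len(L) - 1L + j - 4L) %% L) + 1L
      logw <- logw + bias$motif_weights[b[idx], j]
    }
  }
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Simulate biased insertion events
#'
#' Draws `n` independent insertion positions from the bias model's
#' per-position weights, assigns orientations Bernoulli(0.5), and labels
#' each event with a target-site duplication: the 8-mer starting at the
#' insertion position with probability `tsd_fidelity`, otherwise an
#' exact duplication of aberrant length (0--7, 9 or 10 bp).
#'
#' @param plasmid A [target_plasmid()].
#' @param n Number of events (>= 0).
#' @param bias A [bias_model()].
#' @param seed Integer seed or `NULL`.
#' @param experiment Experiment label attached to every event.
#' @return `data.frame` with columns `event_id`, `position` (0-based),
#'   `orientation` (`+`/`-`), `tsd_seq`, `tsd_len`, `canonical`,
#'   `experiment`.  Orientation `+` means the transposon left arm abuts
#'   the lower-coordinate flank.
#' @export
simulate_insertions <- function(plasmid, n, bias = bias_model(),
                                seed = NULL, experiment = "exp1") {
  stopifnot(inherits(plasmid, "target_plasmid"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != floor(n) || n < 0) {
    abort("`n` must be a single integer >= 0", "invalid_argument")
  }
  n <- as.integer(n)
  if (n == 0L) {
    return(data.frame(event_id = character(), position = integer(),
                      orientation = character(), tsd_seq = character(),
                      tsd_len = integer(), canonical = logical(),
                      experiment = character(), stringsAsFactors = FALSE))
  }
  w <- position_weights(plasmid, bias)
  with_seed(seed, {
    pos <- sample.int(plasmid$length, n, replace = TRUE, prob = w) - 1L
    orient <- sample(c("+", "-"), n, replace = TRUE)
    canonical <- stats::runif(n) < bias$tsd_fidelity
    tsd_len <- ifelse(canonical, 8L,
                      sample(c(0:7, 9L, 10L), n, replace = TRUE))
    tsd_seq <- vapply(seq_len(n), function(i) {
      subseq_circ(plasmid$sequence, pos[i], tsd_len[i])
    }, character(1))
    data.frame(
      event_id = sprintf("%s_evt%05d", experiment, seq_len(n)),
      position = pos,
      orientation = orient,
      tsd_seq = tsd_seq,
      tsd_len = as.integer(tsd_len),
      canonical = canonical,
      experiment = experiment,
      stringsAsFactors = FALSE
    )
  })
}

#' Transposon terminal sequences
#'
#' Holds the outermost sequence of each transposon arm as read inward
#' from the junction: the left terminal on the transposon top strand and
#' the right terminal on the bottom strand (both therefore start at the
#' outermost junction base).  Defaults are the miniTol2 ends: a 261-bp
#' left arm beginning `CAGAGGTGTAAAGTACTTGA` and a 192-bp right arm
#' whose outward-reading terminal begins `CAGAGGTGTAAAAAGTACTC`.
#'
#' @param left_terminal,right_terminal Terminal sequences (distinct).
#' @param left_arm_len,right_arm_len Full arm lengths in bp.
#' @return An object of class `transposon_ends`.
#' @export
transposon_ends <- function(left_terminal = "CAGAGGTGTAAAGTACTTGA",
                            right_terminal = "CAGAGGTGTAAAAAGTACTC",
                            left_arm_len = 261L, right_arm_len = 192L) {
  left_terminal <- toupper(left_terminal)
  right_terminal <- toupper(right_terminal)
  if (!is_dna(left_terminal) || !is_dna(right_terminal)) {
    abort("terminal sequences must be DNA over {A,C,G,T}",
          "invalid_argument")
  }
  if (identical(left_terminal, right_terminal)) {
    abort("left and right terminals must be distinct", "invalid_argument")
  }
  structure(list(left_terminal = left_terminal,
                 right_terminal = right_terminal,
                 left_arm_len = as.integer(left_arm_len),
                 right_arm_len = as.integer(right_arm_len)),
            class = "transposon_ends")
}

#' Emit junction reads for simulated insertion events
#'
#' Produces two records per event -- one per transposon end -- each
#' written 5' to 3' starting inside the transposon terminal and reading
#' outward across the junction into the target flank (the strand a
#' sequencing primer sitting in the transposon would read).  The record
#' therefore begins with the reverse complement of the stored terminal
#' followed by `flank_len` bases of target sequence, wrapping circular
#' coordinates as needed.  Record ids are `<event_id>|left` and
#' `<event_id>|right`.
#'
#' On the plasmid plus strand the left junction flank ends with the
#' duplicated target word and the right junction flank begins with it,
#' mirroring the printed layout of sequenced integration junctions
#' (upstream-TSD-transposon-TSD-downstream).
#'
#' @param events Event `data.frame` from [simulate_insertions()].
#' @param plasmid A [target_plasmid()].
#' @param ends A [transposon_ends()].
#' @param flank_len Target flank length in bp (>= 12, the TSD search
#'   window; shorter flanks are unparseable downstream).
#' @return `data.frame` with columns `id`, `side`, `sequence`,
#'   `event_id`, `experiment`.
#' @export
emit_junction_reads <- function(events, plasmid, ends = transposon_ends(),
                                flank_len = 30) {
  stopifnot(inherits(plasmid, "target_plasmid"),
            inherits(ends, "transposon_ends"))
  flank_len <- check_count(flank_len, "flank_len", min = 0)
  if (flank_len < 12L) {
    abort("`flank_len` must be >= 12 bp (the TSD search window)",
          "invalid_argument")
  }
  n <- nrow(events)
  seqs <- character(2L * n)
  ids <- character(2L * n)
  sides <- character(2L * n)
  rc_left <- revcomp(ends$left_terminal)
  rc_right <- revcomp(ends$right_terminal)
  for (i in seq_len(max(n, 0L))) {
    p <- events$position[i]
    k <- events$tsd_len[i]
    upstream <- subseq_circ(plasmid$sequence, p + k - flank_len, flank_len)
    downstream <- subseq_circ(plasmid$sequence, p, flank_len)
    if (events$orientation[i] == "+") {
      left_seq <- paste0(rc_left, revcomp(upstream))
      right_seq <- paste0(rc_right, downstream)
    } else {
      left_seq <- paste0(rc_left, downstream)
      right_seq <- paste0(rc_right, revcomp(upstream))
    }
    ids[2L * i - 1L] <- paste0(events$event_id[i], "|left")
    ids[2L * i] <- paste0(events$event_id[i], "|right")
    sides[2L * i - 1L] <- "left"
    sides[2L * i] <- "right"
    seqs[2L * i - 1L] <- left_seq
    seqs[2L * i] <- right_seq
  }
  data.frame(
    id = ids,
    side = sides,
    sequence = seqs,
    event_id = rep(events$event_id, each = 2L),
    experiment = rep(events$experiment, each = 2L),
    stringsAsFactors = FALSE
  )
}
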