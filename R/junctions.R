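#' Split a junction read into transposon side and target flank
#'
#' Locates one transposon terminal (or its reverse complement) inside
#' the record by exact match of the terminal's outermost
#' `min_terminal_match` bases, and returns which transposon side it is
#' together with the target flank distal to the terminal.  The returned
#' flank is oriented outward: its first base is the target base adjacent
#' to the transposon, reading away from it.
#'
#' Records in which neither terminal is found at the required exact
#' length raise an `unparseable_junction` condition (such records are
#' counted by [map_junctions()], never silently dropped); records
#' containing both terminals raise `chimera_junction`.  `N`-containing
#' terminals never match (exact search), so all-`N` records are
#' unparseable.
#'
#' @param sequence Junction read (character; lowercase accepted; may
#'   contain `N`).
#' @param ends A [transposon_ends()].
#' @param min_terminal_match Minimum exact terminal anchor length in bp
#'   (>= 12; default 14).
#' @return List with `side` (`"left"`/`"right"`) and `flank`
#'   (outward-oriented target sequence).
#' @export
parse_junction <- function(sequence, ends = transposon_ends(),
                           min_terminal_match = 14) {
  stopifnot(inherits(ends, "transposon_ends"))
  min_terminal_match <- check_count(min_terminal_match,
                                    "min_terminal_match", min = 1)
  if (min_terminal_match < 12L) {
    abort("`min_terminal_match` must be >= 12", "invalid_argument")
  }
  seqstr <- toupper(sequence)
  if (nchar(seqstr) == 0L || !is_dna(seqstr, allow_n = TRUE)) {
    abort("junction sequence must be non-empty DNA over {A,C,G,T,N}",
          "invalid_argument")
  }
  hits <- lapply(c(left = ends$left_terminal, right = ends$right_terminal),
                 function(term) {
    if (nchar(term) < min_terminal_match) {
      abort("terminal shorter than `min_terminal_match`",
            "invalid_argument")
    }
    anchor <- substr(term, 1L, min_terminal_match)
    find_terminal(seqstr, anchor)
  })
  found <- !vapply(hits, is.null, logical(1))
  if (sum(found) == 0L) {
    abort("no transposon terminal found in junction read",
          "unparseable_junction")
  }
  if (sum(found) == 2L) {
    abort("both transposon terminals found: chimeric junction read",
          "chimera_junction")
  }
  side <- names(hits)[found]
  hit <- hits[[side]]
  flank <- if (hit$orientation == "outward") {
    # record reads out of the transposon: flank follows the terminal
    substr(seqstr, hit$end + 1L, nchar(seqstr))
  } else {
    # record reads into the transposon: flank precedes it; flip so the
    # transposon-adjacent base comes first
    revcomp(substr(seqstr, 1L, hit$start - 1L))
  }
  if (nchar(flank) == 0L) {
    abort("terminal found but no target flank in junction read",
          "unparseable_junction")
  }
  list(side = unname(side), flank = flank)
}

# Search for a terminal anchor in either reading direction.  The anchor
# is the outermost `m` bases of the terminal reading inward, so in an
# outward-reading record its reverse complement appears immediately
# before the flank.
find_terminal <- function(seqstr, anchor) {
  rc <- revcomp(anchor)
  m_out <- regexpr(rc, seqstr, fixed = TRUE)
  if (m_out > 0L) {
    return(list(orientation = "outward",
                start = as.integer(m_out),
                end = as.integer(m_out) + nchar(rc) - 1L))
  }
  m_in <- regexpr(anchor, seqstr, fixed = TRUE)
  if (m_in > 0L) {
    return(list(orientation = "inward",
                start = as.integer(m_in),
                end = as.integer(m_in) + nchar(anchor) - 1L))
  }
  NULL
}

#' Map a target flank onto the circular plasmid
#'
#' Exact substring search of the flank's anchor (its first `min_anchor`
#' bases, i.e. those nearest the transposon) against the doubled plasmid
#' sequence -- doubling makes matches spanning the origin visible -- and
#' against its reverse complement.  A unique hit yields the mapping;
#' multiple distinct hits are flagged `ambiguous` and the
#' lowest-coordinate hit is reported (ambiguous mappings are excluded
#' from downstream statistics).
#'
#' @param flank Outward-oriented flank from [parse_junction()].
#' @param plasmid A [target_plasmid()].
#' @param min_anchor Anchor length in bp (default 16).
#' @return List of class `flank_mapping`: `position` (0-based plasmid
#'   coordinate of the flank base adjacent to the transposon), `strand`
#'   (`+` if the outward flank runs in increasing plasmid coordinates),
#'   `match_len`, `ambiguous`, `flank`.
#' @export
map_flank <- function(flank, plasmid, min_anchor = 16) {
  stopifnot(inherits(plasmid, "target_plasmid"))
  min_anchor <- check_count(min_anchor, "min_anchor", min = 1)
  flank <- toupper(flank)
  if (nchar(flank) < min_anchor) {
    abort("flank shorter than `min_anchor`", "invalid_argument")
  }
  anchor <- substr(flank, 1L, min_anchor)
  if (grepl("N", anchor, fixed = TRUE)) {
    abort("flank anchor contains N: unparseable", "unparseable_junction")
  }
  L <- plasmid$length
  doubled <- Biostrings::DNAString(paste0(plasmid$sequence,
                                          plasmid$sequence))
  plus <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::DNAString(anchor), doubled))
  plus <- (plus - 1L)[plus - 1L < L]  # 0-based starts, dedup the doubling
  minus <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::DNAString(revcomp(anchor)),
                             doubled))
  minus <- (minus - 1L)[minus - 1L < L]
  hits <- rbind(
    if (length(plus)) data.frame(position = plus, strand = "+"),
    if (length(minus)) data.frame(position = (minus + min_anchor - 1L) %% L,
                                  strand = "-")
  )
  if (is.null(hits) || nrow(hits) == 0L) {
    abort("flank anchor not found on the plasmid", "unmapped_flank")
  }
  hits <- unique(hits)
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  structure(list(position = as.integer(hits$position[1]),
                 strand = hits$strand[1],
                 match_len = min_anchor,
                 ambiguous = nrow(hits) > 1L,
                 flank = flank),
            class = "flank_mapping")
}

#' Call an insertion event from a mapped junction pair
#'
#' Combines the left- and right-junction flank mappings of one
#' integration product into an insertion event.  Orientation follows
#' from the strand pair (`+` when the left arm abuts the
#' lower-coordinate flank).  The duplication length `k` follows from the
#' circular geometry of the two transposon-adjacent coordinates; the
#' insertion position is the start of the duplicated target word.  The
#' two read flanks are then compared with [detect_tsd()] and the event
#' is canonical iff `k == 8` and the two duplication copies agree.
#'
#' Pairs whose mapped geometry is inconsistent with any duplication
#' length in `[0, max_tsd]` (including same-strand pairs) raise a
#' `discordant_pair` condition.
#'
#' @param left,right `flank_mapping` objects for the left and right
#'   junction records of the same integration product.
#' @param plasmid A [target_plasmid()].
#' @param max_tsd Maximum duplication length considered (default 12).
#' @return One-row event `data.frame` (columns as in
#'   [simulate_insertions()], without `event_id`/`experiment`).
#' @export
call_insertion <- function(left, right, plasmid, max_tsd = 12) {
  stopifnot(inherits(left, "flank_mapping"),
            inherits(right, "flank_mapping"),
            inherits(plasmid, "target_plasmid"))
  max_tsd <- check_count(max_tsd, "max_tsd", min = 0)
  L <- plasmid$length
  if (left$strand == "-" && right$strand == "+") {
    orientation <- "+"
    p_in <- right$position   # downstream flank start = duplication start
    p_out <- left$position   # upstream flank base adjacent to transposon
    up_flank <- revcomp(left$flank)
    down_flank <- right$flank
  } else if (left$strand == "+" && right$strand == "-") {
    orientation <- "-"
    p_in <- left$position
    p_out <- right$position
    up_flank <- revcomp(right$flank)
    down_flank <- left$flank
  } else {
    abort("junction pair maps to the same strand: discordant",
          "discordant_pair")
  }
  k <- as.integer((p_out - p_in + 1L) %% L)
  if (k > max_tsd) {
    abort(sprintf(
      "flank geometry implies duplication length %d > max_tsd: discordant",
      k), "discordant_pair")
  }
  scan_len <- min(max_tsd, nchar(up_flank), nchar(down_flank))
  call <- detect_tsd(up_flank, down_flank, max_len = scan_len)
  data.frame(
    position = p_in,
    orientation = orientation,
    tsd_seq = substr(down_flank, 1L, k),
    tsd_len = k,
    canonical = k == 8L && call$tsd_len >= 8L,
    stringsAsFactors = FALSE
  )
}

#' Map a junction library to insertion events with full accounting
#'
#' Runs parse -> map -> call over a table of junction reads, pairing the
#' two records of each integration product by their shared id prefix
#' (`<pair>|left` / `<pair>|right`).  Every input record ends up in
#' exactly one category: part of a called event, or rejected as
#' `unparseable`, `chimeric`, `unmapped`, `ambiguous`, `discordant`, or
#' `orphan` (its mate failed or is missing).  Ambiguously mapped flanks
#' are reported but never used in statistics.
#'
#' @param records `data.frame` with columns `id`, `sequence` and
#'   optionally `experiment`.
#' @param plasmid A [target_plasmid()].
#' @param ends A [transposon_ends()].
#' @param min_terminal_match,min_anchor,max_tsd Stage parameters, see
#'   [parse_junction()], [map_flank()], [call_insertion()].
#' @return List with `events` (event `data.frame`, `event_id` = pair
#'   id), `rejects` (`data.frame` of `id`, `reason`), and `counts`
#'   (named integer vector over all categories, summing to
#'   `nrow(records)`).
#' @export
map_junctions <- function(records, plasmid, ends = transposon_ends(),
                          min_terminal_match = 14, min_anchor = 16,
                          max_tsd = 12) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  if (is.null(records$experiment)) records$experiment <- "exp1"
  n <- nrow(records)
  status <- rep(NA_character_, n)
  parsed <- vector("list", n)
  mapped <- vector("list", n)
  for (i in seq_len(n)) {
    p <- tryCatch(parse_junction(records$sequence[i], ends,
                                 min_terminal_match),
                  unparseable_junction = function(e) "unparseable",
                  chimera_junction = function(e) "chimeric")
    if (is.character(p)) {
      status[i] <- p
      next
    }
    parsed[[i]] <- p
    m <- tryCatch(map_flank(p$flank, plasmid, min_anchor),
                  unmapped_flank = function(e) "unmapped",
                  unparseable_junction = function(e) "unparseable",
                  invalid_argument = function(e) "unmapped")
    if (is.character(m)) {
      status[i] <- m
      next
    }
    if (m$ambiguous) {
      status[i] <- "ambiguous"
      next
    }
    mapped[[i]] <- m
  }
  pair_id <- sub("\\|(left|right)$", "", records$id)
  events <- list()
  for (pid in unique(pair_id)) {
    idx <- which(pair_id == pid)
    ok <- idx[is.na(status[idx])]
    sides <- vapply(parsed[ok], function(p) if (is.null(p)) NA_character_
                    else p$side, character(1))
    li <- ok[which(sides == "left")]
    ri <- ok[which(sides == "right")]
    if (length(li) != 1L || length(ri) != 1L) {
      status[ok] <- "orphan"
      next
    }
    ev <- tryCatch(call_insertion(mapped[[li]], mapped[[ri]], plasmid,
                                  max_tsd),
                   discordant_pair = function(e) "discordant")
    if (is.character(ev)) {
      status[c(li, ri)] <- ev
      next
    }
    ev$event_id <- pid
    ev$experiment <- records$experiment[li]
    status[c(li, ri)] <- "called"
    events[[length(events) + 1L]] <- ev
  }
  events <- if (length(events)) {
    ev <- do.call(rbind, events)
    ev[, c("event_id", "position", "orientation", "tsd_seq", "tsd_len",
           "canonical", "experiment")]
  } else {
    data.frame(event_id = character(), position = integer(),
               orientation = character(), tsd_seq = character(),
               tsd_len = integer(), canonical = logical(),
               experiment = character(), stringsAsFactors = FALSE)
  }
  categories <- c("called", "unparseable", "chimeric", "unmapped",
                  "ambiguous", "discordant", "orphan")
  counts <- stats::setNames(
    as.integer(table(factor(status, levels = categories))), categories)
  rejects <- data.frame(id = records$id[status != "called"],
                        reason = status[status != "called"],
                        stringsAsFactors = FALSE)
  list(events = events, rejects = rejects, counts = counts)
}
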