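#' Call insertion hotspots
#'
#' A position is a hotspot iff (a) events at that position occur in at
#' least two distinct experiments, in any orientations
#' (`multi-experiment`), or (b) events at that position within a single
#' experiment occur in both orientations
#' (`bidirectional-within-experiment`).  When both clauses hold the
#' multi-experiment rule is reported.  "Position" means the exact first
#' base of the duplicated target word; with `tolerance > 0`, positions
#' within `tolerance` bp of each other (single-linkage on the sorted
#' positions) are grouped and the group is reported at its lowest
#' coordinate.
#'
#' The call is invariant to the order of the input events and to any
#' relabeling of the experiment identifiers.
#'
#' @param events Event `data.frame` with columns `position`,
#'   `orientation`, `experiment`.
#' @param tolerance Grouping half-width in bp (default 0 = exact
#'   position).
#' @return `data.frame` with columns `position`, `n_events`,
#'   `n_experiments`, `orientations`, `rule`, plus a list-column
#'   `support` holding each hotspot's supporting
#'   `(experiment, orientation)` pairs.  Empty input gives an empty
#'   frame.
#' @export
call_hotspots <- function(events, tolerance = 0) {
  tolerance <- check_count(tolerance, "tolerance", min = 0)
  empty <- data.frame(position = integer(), n_events = integer(),
                      n_experiments = integer(), orientations = character(),
                      rule = character(), stringsAsFactors = FALSE)
  empty$support <- list()
  if (is.null(events) || nrow(events) == 0L) return(empty)
  ev <- events[order(events$position, events$experiment,
                     events$orientation), , drop = FALSE]
  if (tolerance == 0L) {
    group <- ev$position
  } else {
    pos <- ev$position
    brk <- c(TRUE, diff(pos) > tolerance)
    group <- stats::ave(pos, cumsum(brk), FUN = min)
  }
  out <- lapply(split(ev, group), function(g) {
    n_exp <- length(unique(g$experiment))
    bidir <- any(vapply(split(g$orientation, g$experiment),
                        function(o) all(c("+", "-") %in% o), logical(1)))
    rule <- if (n_exp >= 2L) "multi-experiment"
            else if (bidir) "bidirectional-within-experiment"
            else NA_character_
    if (is.na(rule)) return(NULL)
    res <- data.frame(position = min(g$position),
                      n_events = nrow(g),
                      n_experiments = n_exp,
                      orientations = paste(sort(unique(g$orientation)),
                                           collapse = ""),
                      rule = rule,
                      stringsAsFactors = FALSE)
    res$support <- list(g[, c("experiment", "orientation")])
    res
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}
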