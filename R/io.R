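#' Write a plasmid to FASTA with GFF3/BED feature annotations
#'
#' The sequence goes to FASTA via Biostrings; features go to GFF3
#' and/or BED via rtracklayer, converted to the formats' native 1-based
#' (GFF3) and 0-based (BED) coordinates.  A feature wrapping the origin
#' is exported as two part-ranges sharing its name (`<name>` with
#' `part` attributes 1 and 2); [read_plasmid()] reassembles them.
#'
#' @param plasmid A [target_plasmid()].
#' @param fasta Path for the FASTA file.
#' @param gff3,bed Optional paths for feature annotation files.
#' @return Invisibly, the FASTA path.
#' @export
write_plasmid <- function(plasmid, fasta, gff3 = NULL, bed = NULL) {
  stopifnot(inherits(plasmid, "target_plasmid"))
  dna <- Biostrings::DNAStringSet(plasmid$sequence)
  names(dna) <- plasmid$name
  Biostrings::writeXStringSet(dna, fasta)
  if (!is.null(gff3) || !is.null(bed)) {
    gr <- features_to_granges(plasmid)
    if (!is.null(gff3)) rtracklayer::export(gr, gff3, format = "gff3")
    if (!is.null(bed)) rtracklayer::export(gr, bed, format = "bed")
  }
  invisible(fasta)
}

features_to_granges <- function(plasmid) {
  f <- plasmid$features
  L <- plasmid$length
  lens <- feature_lengths(plasmid)
  rows <- list()
  for (i in seq_len(nrow(f))) {
    s <- f$start[i]; e <- s + lens[[i]]
    if (e <= L) {
      rows[[length(rows) + 1L]] <-
        data.frame(start = s + 1L, end = e, name = f$name[i],
                   strand = f$strand[i], part = NA_integer_)
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(start = s + 1L, end = L, name = f$name[i],
                   strand = f$strand[i], part = 1L)
      rows[[length(rows) + 1L]] <-
        data.frame(start = 1L, end = e - L, name = f$name[i],
                   strand = f$strand[i], part = 2L)
    }
  }
  rows <- do.call(rbind, rows)
  strand <- ifelse(rows$strand == ".", "*", rows$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = plasmid$name,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = strand,
    seqlengths = stats::setNames(plasmid$length, plasmid$name))
  gr$Name <- rows$name
  gr$type <- "region"
  gr$part <- rows$part
  gr
}

#' Read a plasmid from FASTA (+ optional GFF3/BED features)
#'
#' @param fasta FASTA path (first record used).
#' @param features Optional GFF3 or BED path written by
#'   [write_plasmid()].
#' @return A [target_plasmid()].
#' @export
read_plasmid <- function(fasta, features = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta)
  name <- sub("\\s.*$", "", names(dna)[1])
  sequence <- as.character(dna[[1]])
  feat_df <- NULL
  if (!is.null(features)) {
    gr <- rtracklayer::import(features)
    nm <- if (!is.null(gr$Name)) gr$Name else gr$name
    df <- data.frame(
      name = as.character(nm),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
      stringsAsFactors = FALSE)
    # reassemble origin-wrapping features exported as two parts
    feat_df <- do.call(rbind, lapply(split(df, df$name), function(g) {
      if (nrow(g) == 1L) return(g)
      g <- g[order(g$start), ]
      data.frame(name = g$name[1], start = g$start[nrow(g)],
                 end = g$end[1], strand = g$strand[1],
                 stringsAsFactors = FALSE)
    }))
    feat_df <- feat_df[order(feat_df$start), , drop = FALSE]
  }
  target_plasmid(name, sequence, feat_df)
}

#' Write junction reads as FASTA
#'
#' Headers carry the record id plus `experiment=` metadata so
#' [read_junction_fasta()] round-trips the table.
#'
#' @param reads `data.frame` from [emit_junction_reads()] (columns `id`,
#'   `sequence`, optionally `experiment`).
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_junction_fasta <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$sequence)
  exp <- if (is.null(reads$experiment)) "exp1" else reads$experiment
  names(dna) <- paste0(reads$id, " experiment=", exp)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read junction reads from FASTA
#'
#' @param path FASTA path.
#' @return `data.frame` with columns `id`, `sequence`, `experiment`.
#' @export
read_junction_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  headers <- names(dna)
  id <- sub("\\s.*$", "", headers)
  exp <- ifelse(grepl("experiment=", headers),
                sub(".*experiment=(\\S+).*", "\\1", headers), "exp1")
  data.frame(id = id, sequence = as.character(dna), experiment = exp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read insertion event tables as TSV
#'
#' @param events Event `data.frame`.
#' @param path TSV path.
#' @return Invisibly `path`; `read_events_tsv()` returns the
#'   `data.frame`.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write hotspots as BED
#'
#' One 1-bp interval per hotspot; `name` is the rule fired, `score` the
#' number of supporting events.
#'
#' @param hotspots Output of [call_hotspots()].
#' @param plasmid A [target_plasmid()].
#' @param path BED path.
#' @return Invisibly, `path`.
#' @export
write_hotspots_bed <- function(hotspots, plasmid, path) {
  stopifnot(inherits(plasmid, "target_plasmid"))
  if (nrow(hotspots) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = plasmid$name,
    ranges = IRanges::IRanges(start = hotspots$position + 1L, width = 1L),
    seqlengths = stats::setNames(plasmid$length, plasmid$name))
  gr$name <- hotspots$rule
  gr$score <- hotspots$n_events
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
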