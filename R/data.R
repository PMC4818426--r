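#' Sequenced germline integration junction flanks
#'
#' The eight published junction flank pairs from Tol2 germline
#' integration sites cloned out of F1 transgenic zebrafish: for each
#' site, the 18 bp of genomic sequence ending at the transposon 5'
#' junction (`left_flank`, which ends with the duplicated word) and the
#' 18 bp starting at the 3' junction (`right_flank`, which begins with
#' it), plus chromosome and locus annotation.  Running [detect_tsd()]
#' over these pairs recovers an 8-bp duplication at every site -- the
#' hAT signature.
#'
#' @return `data.frame` with columns `site`, `left_flank`,
#'   `right_flank`, `chromosome`, `locus`.
#' @examples
#' pairs <- germline_junction_pairs()
#' detect_tsd(pairs$left_flank[1], pairs$right_flank[1])
#' @export
germline_junction_pairs <- function() {
  utils::read.delim(
    system.file("extdata", "germline_junctions.tsv",
                package = "tol2sites"),
    stringsAsFactors = FALSE
  )
}
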