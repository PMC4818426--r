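#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis; serializable to
#' YAML so each run can write its effective configuration next to its
#' outputs.  Each randomized stage derives its own seed
#' deterministically from `seed` plus a stage offset, so any stage can
#' be re-run in isolation and reproduce its output.
#'
#' @param seed Master integer seed.
#' @param out_dir Output directory for [run_pipeline()].
#' @param plasmid_length Synthetic plasmid length in bp.
#' @param feature_spec Feature layout for [make_target_plasmid()].
#' @param n_events Total simulated insertions across experiments.
#' @param n_experiments Number of independent experiments the events are
#'   split across.
#' @param beta_at,window,tsd_fidelity Bias-model parameters, see
#'   [bias_model()].
#' @param flank_len Junction flank length in bp.
#' @param min_terminal_match,min_anchor,max_tsd Mapping parameters.
#' @param n_sims Monte Carlo simulations for the bias test.
#' @param hotspot_tolerance Hotspot grouping half-width in bp.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 42,
                       out_dir = tempfile("tol2sites_run_"),
                       plasmid_length = 4000,
                       feature_spec = default_feature_spec(),
                       n_events = 500,
                       n_experiments = 4,
                       beta_at = 8,
                       window = 51,
                       tsd_fidelity = 0.86,
                       flank_len = 30,
                       min_terminal_match = 14,
                       min_anchor = 16,
                       max_tsd = 12,
                       n_sims = 10000,
                       hotspot_tolerance = 0) {
  structure(list(
    seed = as.integer(seed), out_dir = out_dir,
    plasmid_length = as.integer(plasmid_length),
    feature_spec = as.data.frame(feature_spec),
    n_events = as.integer(n_events),
    n_experiments = as.integer(n_experiments),
    beta_at = beta_at, window = as.integer(window),
    tsd_fidelity = tsd_fidelity, flank_len = as.integer(flank_len),
    min_terminal_match = as.integer(min_terminal_match),
    min_anchor = as.integer(min_anchor), max_tsd = as.integer(max_tsd),
    n_sims = as.integer(n_sims),
    hotspot_tolerance = as.integer(hotspot_tolerance)
  ), class = "run_config")
}

#' Default synthetic plasmid layout
#'
#' A pGL-like circular target: an AT-rich SV40 polyA segment (64% AT)
#' next to ampR, ori and backbone segments at average composition.
#'
#' @return `data.frame` with columns `name`, `fraction`, `at`.
#' @export
default_feature_spec <- function() {
  data.frame(
    name = c("sv40_polyA", "ampR", "ori", "backbone"),
    fraction = c(0.10, 0.25, 0.15, 0.50),
    at = c(0.64, 0.50, 0.50, 0.50),
    stringsAsFactors = FALSE
  )
}

stage_seed <- function(config, stage) {
  offsets <- c(plasmid = 1L, events = 2L, bias_test = 3L)
  (config$seed + 10007L * offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full synthetic-to-report pipeline
#'
#' Generates a synthetic plasmid and insertion events, emits junction
#' reads, then runs the analysis chain map-junctions -> TSD summary ->
#' feature occupancy -> Monte Carlo bias test -> hotspots -> motif ->
#' AT enrichment, writing every intermediate in a standard format
#' (FASTA, GFF3, BED, TSV) plus a machine-readable `summary.json` and
#' the effective `config.yaml` into `config$out_dir`.  Record
#' conservation is part of the summary: every junction record is
#' accounted for as called or rejected with a reason.
#'
#' @param config A [run_config()].
#' @return Invisibly, the summary list (with `out_dir` attached).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  plasmid <- make_target_plasmid(config$plasmid_length,
                                 config$feature_spec,
                                 seed = stage_seed(config, "plasmid"))
  write_plasmid(plasmid, out("plasmid.fa"), gff3 = out("features.gff3"),
                bed = out("features.bed"))

  bias <- bias_model(beta_at = config$beta_at, window = config$window,
                     tsd_fidelity = config$tsd_fidelity)
  per_exp <- diff(round(seq(0, config$n_events,
                            length.out = config$n_experiments + 1L)))
  truth <- do.call(rbind, lapply(seq_len(config$n_experiments),
    function(i) {
      simulate_insertions(plasmid, per_exp[i], bias,
                          seed = stage_seed(config, "events") + i,
                          experiment = sprintf("exp%d", i))
    }))
  write_events_tsv(truth, out("events_truth.tsv"))

  reads <- emit_junction_reads(truth, plasmid, transposon_ends(),
                               config$flank_len)
  write_junction_fasta(reads, out("junctions.fa"))

  mapped <- map_junctions(reads, plasmid, transposon_ends(),
                          config$min_terminal_match, config$min_anchor,
                          config$max_tsd)
  write_events_tsv(mapped$events, out("events.tsv"))
  write_events_tsv(mapped$rejects, out("rejects.tsv"))

  rate <- if (nrow(mapped$events) > 0) tsd_rate(mapped$events) else
    list(fraction_canonical = NaN, n = 0L, counts_by_length = integer())

  occ <- feature_occupancy(mapped$events, plasmid)
  write_events_tsv(occ, out("occupancy.tsv"))
  mc <- monte_carlo_bias_test(occ, n_sims = config$n_sims,
                              seed = stage_seed(config, "bias_test"))
  write_events_tsv(as.data.frame(mc), out("bias_test.tsv"))

  hs <- call_hotspots(mapped$events, tolerance = config$hotspot_tolerance)
  write_hotspots_bed(hs, plasmid, out("hotspots.bed"))
  write_events_tsv(hs[, setdiff(names(hs), "support")],
                   out("hotspots.tsv"))

  motif <- suppressWarnings(build_motif(mapped$events, plasmid))
  utils::write.table(motif$counts, out("motif_counts.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  writeLines(motif$consensus, out("consensus.txt"))

  at <- at_enrichment(mapped$events, plasmid, config$window)

  summary <- list(
    seed = config$seed,
    n_records_in = nrow(reads),
    n_events_called = nrow(mapped$events),
    record_counts = as.list(mapped$counts),
    canonical_tsd_fraction = rate$fraction_canonical,
    tsd_length_counts = as.list(rate$counts_by_length),
    occupancy = stats::setNames(as.list(occ$observed), occ$feature),
    p_greater = stats::setNames(as.list(mc$p_greater), mc$feature),
    p_less = stats::setNames(as.list(mc$p_less), mc$feature),
    n_sims = config$n_sims,
    hotspot_count = nrow(hs),
    consensus = motif$consensus,
    motif_n_sites = motif$n_sites,
    site_at = at$site_at,
    background_at = at$background_at
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(config), out("config.yaml"))
  summary$out_dir <- config$out_dir
  invisible(summary)
}

#' Render a human-readable report for a pipeline run
#'
#' Tabulates record accounting, the TSD summary, occupancy vs
#' expectation with Monte Carlo p-values, hotspots, and the observed
#' consensus against the reference `TNA(C/G)TTATAA(G/C)TNA`.  Stages
#' whose outputs are missing are marked "not computed" with a
#' partial-report warning.  Regeneration is idempotent.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param path Output path (default `report.md` inside `run_dir`).
#' @return Invisibly, the report path.
#' @export
render_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  have <- function(f) file.exists(file.path(run_dir, f))
  lines <- c("# Insertion-site analysis report", "")
  partial <- FALSE

  if (have("summary.json")) {
    s <- jsonlite::read_json(file.path(run_dir, "summary.json"))
    lines <- c(lines, "## Run overview", "",
               sprintf("- seed: %s", s$seed),
               sprintf("- junction records in: %s", s$n_records_in),
               sprintf("- events called: %s", s$n_events_called), "")
    lines <- c(lines, "## Record accounting", "",
               vapply(names(s$record_counts), function(k) {
                 sprintf("- %s: %s", k, s$record_counts[[k]])
               }, character(1)), "")
    lines <- c(lines, "## Target-site duplications", "",
               sprintf("- canonical 8-bp TSD fraction: %s",
                       format(s$canonical_tsd_fraction)), "")
  } else {
    lines <- c(lines, "## Run overview", "", "not computed", "")
    partial <- TRUE
  }

  if (have("bias_test.tsv")) {
    mc <- read_events_tsv(file.path(run_dir, "bias_test.tsv"))
    lines <- c(lines, "## Feature occupancy vs length-proportional null",
               "",
               "| feature | length | observed | expected | p_greater | p_less |",
               "|---|---|---|---|---|---|",
               vapply(seq_len(nrow(mc)), function(i) {
                 sprintf("| %s | %d | %d | %.1f | %.4g | %.4g |",
                         mc$feature[i], mc$length[i], mc$observed[i],
                         mc$expected[i], mc$p_greater[i], mc$p_less[i])
               }, character(1)), "")
  } else {
    lines <- c(lines, "## Feature occupancy", "", "not computed", "")
    partial <- TRUE
  }

  if (have("hotspots.tsv")) {
    hs <- read_events_tsv(file.path(run_dir, "hotspots.tsv"))
    lines <- c(lines, "## Hotspots", "",
               sprintf("%d hotspot(s) (recurrent across experiments or bidirectional within one).",
                       nrow(hs)), "")
  } else {
    lines <- c(lines, "## Hotspots", "", "not computed", "")
    partial <- TRUE
  }

  if (have("consensus.txt")) {
    cons <- readLines(file.path(run_dir, "consensus.txt"))[1]
    lines <- c(lines, "## Integration-site consensus", "",
               sprintf("- observed:  `%s`", cons),
               sprintf("- reference: `%s` (TNA(C/G)TTATAA(G/C)TNA)",
                       tol2_reference_consensus()),
               sprintf("- compatible with reference: %s",
                       consensus_compatible(cons)), "")
  } else {
    lines <- c(lines, "## Integration-site consensus", "", "not computed",
               "")
    partial <- TRUE
  }

  if (have("summary.json")) {
    s <- jsonlite::read_json(file.path(run_dir, "summary.json"))
    lines <- c(lines, "## AT enrichment", "",
               sprintf("- mean AT fraction around insertion sites: %s",
                       format(s$site_at)),
               sprintf("- plasmid background AT fraction: %s",
                       format(s$background_at)), "")
  }

  if (partial) warning("render_report: some stage outputs missing; report is partial")
  writeLines(lines, path)
  invisible(path)
}
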