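test_that("parse_junction splits terminal from flank in both orientations", {
  ends <- transposon_ends()
  # inward-reading record: flank precedes the terminal
  rec_in <- paste0(revcomp_test("ACGTTCAGTGCCTAAGG"), ends$left_terminal)
  got <- parse_junction(rec_in, ends)
  expect_equal(got$side, "left")
  expect_equal(got$flank, "ACGTTCAGTGCCTAAGG")
  # spec'd trivial layout: terminal followed by flank, outward reading
  rec_out <- paste0(revcomp_test(ends$right_terminal), "ACGTTCAGTGCCT")
  got2 <- parse_junction(rec_out, ends)
  expect_equal(got2$side, "right")
  expect_equal(got2$flank, "ACGTTCAGTGCCT")
})

test_that("unparseable and chimeric records raise classed conditions", {
  ends <- transposon_ends()
  expect_error(parse_junction(strrep("N", 40), ends),
               class = "unparseable_junction")
  expect_error(parse_junction("ACGTACGTACGTACGTACGT", ends),
               class = "unparseable_junction")
  chimera <- paste0(ends$left_terminal, "ACGTACGT", ends$right_terminal)
  expect_error(parse_junction(chimera, ends), class = "chimera_junction")
  expect_error(parse_junction("ACGT", ends, min_terminal_match = 8),
               class = "invalid_argument")
})

test_that("map_flank finds unique, wrapped and ambiguous anchors", {
  p <- toy_plasmid()
  flank <- substr(p$sequence, 101, 125)  # positions 100..124, 0-based
  m <- map_flank(flank, p, min_anchor = 20)
  expect_equal(m$position, 100)
  expect_equal(m$strand, "+")
  expect_false(m$ambiguous)

  # flank spanning the origin, verified against a rotation scan
  wrap_flank <- subseq_circ_test(p$sequence, p$length - 9, 20)
  mw <- map_flank(wrap_flank, p, min_anchor = 20)
  expect_equal(mw$position, p$length - 9)
  hits <- which(vapply(0:(p$length - 1), function(s) {
    subseq_circ_test(p$sequence, s, 20) == wrap_flank
  }, logical(1))) - 1
  expect_equal(mw$position, hits[1])

  # reverse-strand mapping: outward flank on the minus strand
  rc_flank <- revcomp_test(substr(p$sequence, 201, 220))
  mr <- map_flank(rc_flank, p, min_anchor = 20)
  expect_equal(mr$strand, "-")
  expect_equal(mr$position, 219)  # transposon-adjacent base

  expect_error(map_flank("ACGTACGTACGTACGTACGT", p, min_anchor = 30),
               class = "invalid_argument")
})

test_that("repeated anchors are flagged ambiguous, absent ones unmapped", {
  rep_unit <- "ACGTTGCAAGGCTTAACGGT"
  filler1 <- strrep("CT", 40)
  filler2 <- strrep("GA", 40)
  p <- target_plasmid("rep", paste0(rep_unit, filler1, rep_unit, filler2))
  m <- map_flank(rep_unit, p, min_anchor = 20)
  expect_true(m$ambiguous)
  expect_equal(m$position, 0)  # lowest-coordinate hit reported
  expect_error(map_flank(strrep("A", 20), p, min_anchor = 20),
               class = "unmapped_flank")
})

test_that("call_insertion recovers position, TSD and orientation", {
  p <- toy_plasmid()
  ends <- transposon_ends()
  for (orient in c("+", "-")) {
    for (k in c(8L, 0L, 9L)) {
      ev <- manual_events(100, orient, tsd_len = k, plasmid = p)
      rd <- emit_junction_reads(ev, p, ends, flank_len = 24)
      pl <- parse_junction(rd$sequence[1], ends)
      pr <- parse_junction(rd$sequence[2], ends)
      ml <- map_flank(pl$flank, p)
      mr <- map_flank(pr$flank, p)
      got <- call_insertion(ml, mr, p, max_tsd = 12)
      expect_equal(got$position, 100)
      expect_equal(got$orientation, orient)
      expect_equal(got$tsd_len, k)
      expect_equal(got$canonical, k == 8L)
      if (k > 0) {
        expect_identical(got$tsd_seq,
                         subseq_circ_test(p$sequence, 100, k))
      }
    }
  }
})

test_that("impossible flank geometry is discordant", {
  p <- toy_plasmid()
  ends <- transposon_ends()
  ev1 <- manual_events(100, "+", plasmid = p)
  ev2 <- manual_events(600, "+", plasmid = p)
  rd1 <- emit_junction_reads(ev1, p, ends, flank_len = 24)
  rd2 <- emit_junction_reads(ev2, p, ends, flank_len = 24)
  ml <- map_flank(parse_junction(rd1$sequence[1], ends)$flank, p)
  mr <- map_flank(parse_junction(rd2$sequence[2], ends)$flank, p)
  expect_error(call_insertion(ml, mr, p, max_tsd = 12),
               class = "discordant_pair")
})

test_that("perfect-fidelity libraries round-trip exactly", {
  p <- toy_plasmid()
  truth <- simulate_insertions(p, 200, bias_model(tsd_fidelity = 1),
                               seed = 13)
  rd <- emit_junction_reads(truth, p, transposon_ends(), 30)
  m <- map_junctions(rd, p)
  expect_equal(nrow(m$events), nrow(truth))
  got <- m$events[match(truth$event_id, m$events$event_id), ]
  expect_equal(got$position, truth$position)
  expect_equal(got$orientation, truth$orientation)
  expect_equal(got$tsd_seq, truth$tsd_seq)
  expect_true(all(got$canonical))
})

test_that("every record lands in exactly one accounting category", {
  p <- toy_plasmid()
  ends <- transposon_ends()
  truth <- simulate_insertions(p, 30, bias_model(), seed = 17)
  rd <- emit_junction_reads(truth, p, ends, 30)
  # corrupt a few records in distinct ways
  rd$sequence[1] <- strrep("N", 50)                                # unparseable
  rd$sequence[3] <- paste0(ends$left_terminal, "AAGG",
                           ends$right_terminal)                    # chimeric
  rd$sequence[5] <- paste0(revcomp_test(ends$left_terminal),
                           strrep("GATC", 8))                      # likely unmapped
  m <- map_junctions(rd, p)
  expect_equal(sum(m$counts), nrow(rd))
  expect_equal(unname(m$counts["called"]), 2L * nrow(m$events))
  expect_equal(nrow(m$rejects) + unname(m$counts["called"]), nrow(rd))
  expect_gte(unname(m$counts["unparseable"]), 1L)
  expect_gte(unname(m$counts["chimeric"]), 1L)
  expect_gte(unname(m$counts["orphan"]), 1L)
})
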