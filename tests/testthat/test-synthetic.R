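test_that("simulate_insertions handles n = 0 and rejects n < 0", {
  p <- toy_plasmid()
  ev <- simulate_insertions(p, 0, bias_model(), seed = 1)
  expect_equal(nrow(ev), 0)
  expect_error(simulate_insertions(p, -1, bias_model(), seed = 1),
               class = "invalid_argument")
})

test_that("biased sampling matches an explicit weight-vector oracle", {
  p <- toy_plasmid()  # "hot" feature at 90% AT over the first quarter
  beta <- 6; win <- 51
  probs_oracle <- brute_position_probs(p, beta, win)
  probs_pkg <- position_weights(p, bias_model(beta_at = beta, window = win))
  expect_equal(probs_pkg, probs_oracle, tolerance = 1e-12)

  ev <- simulate_insertions(p, 10000, bias_model(beta_at = beta,
                                                 window = win), seed = 5)
  in_hot <- mean(feature_at(p, ev$position) == "hot", na.rm = TRUE)
  expect_gt(in_hot, 0.25)  # exceeds the length fraction
  # agree with the oracle's expected mass in the hot feature
  hot_mass <- sum(probs_oracle[1:500])
  expect_lt(abs(in_hot - hot_mass), 3 * sqrt(hot_mass * (1 - hot_mass) / 10000) + 0.01)
})

test_that("uniform bias gives length-proportional occupancy", {
  p <- toy_plasmid()
  ev <- simulate_insertions(p, 10000, bias_model(beta_at = 0), seed = 9)
  counts <- table(factor(feature_at(p, ev$position),
                         levels = p$features$name))
  expect_gt(stats::chisq.test(counts, p = rep(0.25, 4))$p.value, 0.01)
})

test_that("canonical-TSD fraction tracks the fidelity parameter", {
  p <- toy_plasmid()
  for (fid in c(1, 0.86, 0.5)) {
    ev <- simulate_insertions(p, 2000, bias_model(tsd_fidelity = fid),
                              seed = 21)
    se <- sqrt(max(fid * (1 - fid), 1e-12) / 2000)
    expect_lte(abs(mean(ev$canonical) - fid), max(3 * se, 1e-12))
    expect_true(all(ev$tsd_len[ev$canonical] == 8))
    expect_true(all(ev$tsd_len[!ev$canonical] %in% c(0:7, 9, 10)))
    # the recorded TSD is the plasmid word at the insertion position
    i <- which(ev$tsd_len > 0)[1]
    expect_identical(ev$tsd_seq[i],
                     subseq_circ_test(p$sequence, ev$position[i],
                                      ev$tsd_len[i]))
  }
})

test_that("simulation is reproducible from the seed", {
  p <- toy_plasmid()
  a <- simulate_insertions(p, 100, bias_model(), seed = 77)
  b <- simulate_insertions(p, 100, bias_model(), seed = 77)
  expect_identical(a, b)
})

test_that("junction reads mirror the printed junction layout", {
  p <- toy_plasmid()
  ends <- transposon_ends()
  ev <- manual_events(100, "+", plasmid = p)
  rd <- emit_junction_reads(ev, p, ends, flank_len = 20)
  expect_equal(nrow(rd), 2)
  expect_equal(rd$id, c("ev001|left", "ev001|right"))
  tsd <- subseq_circ_test(p$sequence, 100, 8)
  # plus-strand left flank ends with the TSD, right flank begins with it
  left_flank_plus <- revcomp_test(sub(paste0("^", revcomp_test(ends$left_terminal)),
                                      "", rd$sequence[1]))
  right_flank_plus <- sub(paste0("^", revcomp_test(ends$right_terminal)),
                          "", rd$sequence[2])
  expect_true(endsWith(left_flank_plus, tsd))
  expect_true(startsWith(right_flank_plus, tsd))
})

test_that("flanks wrap the circular origin without truncation", {
  p <- toy_plasmid()
  ev <- manual_events(p$length - 3, "+", plasmid = p)
  rd <- emit_junction_reads(ev, p, transposon_ends(), flank_len = 18)
  expect_true(all(nchar(rd$sequence) ==
                    nchar(revcomp_test(transposon_ends()$left_terminal)) + 18))
  # and the pair still round-trips through mapping
  m <- map_junctions(rd, p)
  expect_equal(m$events$position, p$length - 3)
})

test_that("short flanks are rejected as unparseable downstream", {
  p <- toy_plasmid()
  ev <- manual_events(10, plasmid = p)
  expect_error(emit_junction_reads(ev, p, transposon_ends(), flank_len = 11),
               class = "invalid_argument")
})
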