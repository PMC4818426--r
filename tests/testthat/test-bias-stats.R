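test_that("feature occupancy matches a hand tally and conventions", {
  p <- target_plasmid("x", strrep("ACGT", 30),
                      features = data.frame(name = c("a", "b", "c"),
                                            start = c(0, 40, 80),
                                            end = c(40, 80, 100)))
  # 120-bp plasmid, 20 bp uncovered
  ev <- manual_events(c(0, 5, 39, 40, 41, 79, 80, 99, 100, 110),
                      plasmid = p)
  occ <- feature_occupancy(ev, p)
  expect_equal(occ$feature, c("a", "b", "c", "unannotated"))
  expect_equal(occ$length, c(40L, 40L, 20L, 20L))
  expect_equal(occ$observed, c(3L, 3L, 2L, 2L))  # boundary 40 -> b, 100 -> unannotated
  expect_equal(attr(occ, "n_total"), 10L)

  empty <- feature_occupancy(manual_events(integer(0), plasmid = p), p)
  expect_true(all(empty$observed == 0))

  bad <- target_plasmid("y", strrep("ACGT", 30),
                        features = data.frame(name = c("a", "b"),
                                              start = c(0, 30),
                                              end = c(40, 60)))
  expect_error(feature_occupancy(ev, bad), class = "ambiguous_annotation")
})

test_that("Monte Carlo p-values match closed forms on simple nulls", {
  # single feature covering everything: every simulation ties the observed
  one <- occupancy_table("all", 1000, 20)
  mc1 <- monte_carlo_bias_test(one, n_sims = 500, seed = 4)
  expect_equal(mc1$p_greater, 1)
  expect_equal(mc1$p_less, 1)

  # two equal features, observed (5, 0): P(Binom(5, 1/2) >= 5) = 1/32
  occ <- occupancy_table(c("a", "b"), c(500, 500), c(5, 0))
  mc <- monte_carlo_bias_test(occ, n_sims = 10000, seed = 8)
  p_exact <- 1 / 32
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(mc$p_greater[1] - p_exact), 3 * se + 2 / 10001)

  expect_error(monte_carlo_bias_test(occupancy_table("a", 10, 0)),
               class = "empty_input")
  a <- monte_carlo_bias_test(occ, n_sims = 1000, seed = 3)
  b <- monte_carlo_bias_test(occ, n_sims = 1000, seed = 3)
  expect_identical(a$p_greater, b$p_greater)
})

test_that("exact enumeration oracle reproduces closed-form tails", {
  occ <- occupancy_table(c("a", "b"), c(500, 500), c(5, 0))
  expect_equal(exact_multinomial_tail(occ, "a"), 0.03125, tolerance = 1e-12)
  expect_equal(exact_multinomial_tail(occ, "b"), 1)  # observed 0
  occ3 <- occupancy_table(c("a", "b", "c"), c(500, 300, 200), c(4, 0, 0))
  expect_equal(exact_multinomial_tail(occ3, "a"), 0.5^4, tolerance = 1e-12)
  # against the binomial marginal on a non-degenerate instance
  occ4 <- occupancy_table(c("a", "b", "c"), c(100, 250, 150), c(5, 4, 3))
  expect_equal(exact_multinomial_tail(occ4, "b"),
               stats::pbinom(3, 12, 0.5, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(exact_multinomial_tail(occupancy_table("a", 10, 13), "a"),
               class = "unsupported_size")
})

test_that("Monte Carlo agrees with the exact oracle on enumerable instances", {
  set.seed(31)
  n_sims <- 4000
  for (rep in 1:12) {
    f <- sample(2:4, 1)
    lens <- sample(50:500, f)
    n <- sample(1:12, 1)
    obs <- as.vector(stats::rmultinom(1, n, lens / sum(lens)))
    occ <- occupancy_table(paste0("f", seq_len(f)), lens, obs)
    mc <- monte_carlo_bias_test(occ, n_sims = n_sims,
                                seed = 1000 + rep)
    for (i in seq_len(f)) {
      p_exact <- min(1, exact_multinomial_tail(occ, paste0("f", i)))
      se <- sqrt(p_exact * (1 - p_exact) / n_sims)
      expect_lt(abs(mc$p_greater[i] - p_exact), 3 * se + 2 / (n_sims + 1))
    }
  }
})

test_that("concentrating 75 counts in a quarter-length feature is extreme", {
  occ <- occupancy_table(paste0("f", 1:4), rep(1000L, 4),
                         c(75L, 0L, 0L, 0L))
  mc <- monte_carlo_bias_test(occ, n_sims = 10000, seed = 2)
  expect_lt(mc$p_greater[1], 1e-4)
})
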