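test_that("singleton-flip rate finds the double-crossover motif, bridging gaps", {
  # one sample with the 0 -> 2 -> 0 motif
  gm <- gm_from_codes(cbind(c(0L, 2L, 0L), c(0L, 0L, 0L)))
  r <- singleton_flip_rate(gm)
  expect_equal(r$n_flips, c(0L, 1L, 0L))
  expect_equal(r$flip_rate, c(0, 0.5, 0))

  # constant vectors: no flips anywhere
  r0 <- singleton_flip_rate(gm_from_codes(matrix(2L, 5, 3)))
  expect_true(all(r0$flip_rate == 0))

  # flanks bridge missing bins: 0, NA, 2, NA, 0
  gm2 <- gm_from_codes(cbind(c(0L, NA, 2L, NA, 0L), c(0L, 0L, 0L, 0L, 0L)))
  r2 <- singleton_flip_rate(gm2)
  expect_equal(r2$n_flips, c(0L, 0L, 1L, 0L, 0L))

  expect_error(singleton_flip_rate(gm_from_codes(matrix(0L, 3, 1))),
               "2 samples")
})

test_that("curation masks recurrently flipping bins and is idempotent", {
  # bin 2 flips in 5 of 40 samples (0.125 > 0.1)
  codes <- matrix(0L, nrow = 3, ncol = 40)
  codes[2, 1:5] <- 2L
  gm <- gm_from_codes(codes)
  cur <- curate(gm, max_flip_rate = 0.1)
  expect_true(all(is.na(cur$gm$geno[2, ])))
  expect_identical(cur$report$removed, c(FALSE, TRUE, FALSE))
  expect_equal(cur$report$flip_rate[2], 0.125)

  # idempotent: re-curation changes nothing
  cur2 <- curate(cur$gm, max_flip_rate = 0.1)
  expect_identical(cur2$gm$geno, cur$gm$geno)
  expect_false(any(cur2$report$removed))

  # threshold 1 removes nothing
  expect_false(any(curate(gm, max_flip_rate = 1)$report$removed))

  # an error-free simulation loses no bins at the default threshold
  m <- tiny_map(1, genetic_length = 0.6)
  pop <- simulate_population(m, meiosis_model(nu = 1, genetic_length = 0.6),
                             observation_model(detect_prob = 0.8,
                                               error_rate = 0),
                             n = 30, seed = 112)
  gmc <- bin_consensus(pop$calls, m)
  expect_false(any(curate(gmc, max_flip_rate = 0.1)$report$removed))
})

test_that("event detection scans informative bins and bridges missing data", {
  # the canonical 0 0 0 2 2 2 pattern: one event between bins 3 and 4
  gm <- gm_from_codes(matrix(c(0L, 0L, 0L, 2L, 2L, 2L), ncol = 1))
  ev <- detect_events(gm)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$left, 3e6)
  expect_equal(ev$right, 3e6 + 1)
  expect_equal(ev$midpoint, 3e6 + 0.5)
  expect_identical(ev$from_code, 0L)
  expect_identical(ev$to_code, 2L)

  # constant or all-missing vectors yield nothing
  expect_equal(nrow(detect_events(gm_from_codes(matrix(2L, 6, 1)))), 0L)
  expect_equal(nrow(detect_events(gm_from_codes(matrix(NA_integer_, 6, 1)))),
               0L)

  # 0 NA NA 2: event spans the gap with informative boundaries
  ev2 <- detect_events(gm_from_codes(matrix(c(0L, NA, NA, 2L), ncol = 1)))
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$left, 1e6)
  expect_equal(ev2$right, 3e6 + 1)

  # boundaries are ordered and non-overlapping along a busy vector
  ev3 <- detect_events(gm_from_codes(matrix(c(0L, 2L, NA, 0L, 0L, 2L),
                                            ncol = 1)))
  expect_equal(nrow(ev3), 3L)
  expect_true(all(diff(ev3$midpoint) > 0))
  expect_true(all(ev3$left < ev3$right))
  # alternation: consecutive events flip in opposite directions
  expect_true(all(ev3$from_code[-1] == ev3$to_code[-nrow(ev3)]))
})

test_that("singleton masking suppresses isolated flips but keeps real transitions", {
  v <- c(0L, 0L, 2L, 0L, 0L, 2L, 2L, 2L)
  gm <- gm_from_codes(matrix(v, ncol = 1))
  expect_equal(nrow(detect_events(gm)), 3L)
  ev <- detect_events(gm, mask_singletons = TRUE)
  expect_equal(nrow(ev), 1L)                 # only the terminal 0->2 switch
  expect_identical(ev$from_code, 0L)
})

test_that("true crossovers are recovered at half coverage without errors", {
  m <- tiny_map(2, length = 50e6, spacing = 2e5, genetic_length = 1)
  pop <- simulate_population(m, meiosis_model(nu = 1, genetic_length = 1),
                             observation_model(detect_prob = 0.5,
                                               error_rate = 0),
                             n = 15, seed = 113)
  gm <- bin_consensus(pop$calls, m)
  ev <- detect_events(gm)
  truth <- true_crossovers(pop)
  # no spurious events: per sample/chromosome, detected count <= true count
  tc <- truth[, .N, by = .(sample, chrom)]
  dc <- ev[, .N, by = .(sample, chrom)]
  cmp <- merge(tc, dc, by = c("sample", "chrom"), all = TRUE)
  cmp[is.na(cmp)] <- 0L
  expect_true(all(cmp$N.y <= cmp$N.x))
  # aggregate recall: with clean calls at 0.5 coverage nearly all true
  # crossovers away from chromosome ends are recovered at megabase
  # resolution (one bin of slack: when the crossover-containing bin is
  # itself informative the interval's inner edge can sit one bin away
  # from the true position)
  interior <- truth[midpoint > 2e6 & midpoint < 48e6]
  hits <- 0L
  for (r in seq_len(nrow(interior))) {
    hit <- ev[sample == interior$sample[r] & chrom == interior$chrom[r] &
                left - 1e6 <= interior$midpoint[r] &
                right + 1e6 >= interior$midpoint[r]]
    hits <- hits + (nrow(hit) > 0L)
  }
  expect_gte(hits / nrow(interior), 0.9)
})

test_that("event-count summaries match a brute-force recount", {
  m <- tiny_map(2, genetic_length = 1)
  pop <- simulate_population(m, meiosis_model(nu = 1, genetic_length = 1),
                             observation_model(detect_prob = 0.6,
                                               error_rate = 0),
                             n = 20, seed = 114)
  gm <- bin_consensus(pop$calls, m)
  ev <- detect_events(gm)
  cnt <- count_per_chromosome(ev, pop$samples, m$chromosomes$chrom)

  # independent recount
  brute <- sapply(pop$samples, function(s)
    sapply(m$chromosomes$chrom, function(cc)
      sum(ev$sample == s & ev$chrom == cc)))
  expect_equal(cnt$total_events, sum(brute))
  expect_equal(cnt$mean_per_sample, sum(brute) / length(pop$samples))
  kmax <- max(brute)
  expect_equal(cnt$class_freq$count,
               as.integer(table(factor(brute, levels = 0:kmax))))
  expect_equal(sum(cnt$class_freq$freq), 1)

  # single sample without events: class 0 frequency 1
  c0 <- count_per_chromosome(ev[0], "only", "tc1")
  expect_equal(c0$class_freq$freq, 1)
  expect_equal(c0$mean_per_sample, 0)
})

test_that("chi-square goodness of fit matches hand computations", {
  same <- chi2_goodness_of_fit(c(5, 10, 5), c(10, 20, 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # counts (10, 30) against proportions (0.5, 0.5): ((10-20)^2+(30-20)^2)/20
  h <- chi2_goodness_of_fit(c(10, 30), c(0.5, 0.5))
  expect_equal(h$statistic, 10)
  expect_equal(h$df, 1L)
  expect_equal(h$p_value, stats::pchisq(10, 1, lower.tail = FALSE))

  # two count vectors use the two-sample homogeneity form
  hh <- chi2_goodness_of_fit(c(10, 30), c(20, 20))
  expect_equal(hh$statistic,
               unname(suppressWarnings(
                 stats::chisq.test(rbind(c(10, 30), c(20, 20)),
                                   correct = FALSE)$statistic)))

  # sparse upper tail is pooled so expected counts stay >= 1
  pooled <- chi2_goodness_of_fit(c(50, 30, 1, 0, 1), c(60, 40, 1, 0, 1))
  expect_true(all(pooled$expected >= 1))
  expect_error(chi2_goodness_of_fit(c(0, 0), c(1, 1)), "zero")
})

test_that("chi-square P is calibrated against a fixed reference distribution", {
  set.seed(115)
  # large reference sample pins the class proportions near the truth
  ref <- table(factor(lengths(simulate_chromatids(50000, 1, 2)),
                      levels = 0:8))
  pv <- replicate(400, {
    a <- table(factor(lengths(simulate_chromatids(200, 1, 2)), levels = 0:8))
    chi2_goodness_of_fit(as.integer(a), as.integer(ref))$p_value
  })
  frac05 <- mean(pv < 0.05)
  expect_lt(abs(frac05 - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.02)
  frac30 <- mean(pv < 0.30)
  expect_lt(abs(frac30 - 0.30), 3 * sqrt(0.30 * 0.70 / 400) + 0.02)
})
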