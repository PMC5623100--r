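test_that("inter-crossover distances are adjacent-pair midpoint differences", {
  m <- tiny_map(1, length = 760e6)
  ev <- data.table::data.table(
    sample = c("a", "a", "b", "c", "c", "c"),
    chrom = "tc1",
    midpoint = c(50e6, 650e6, 100e6, 20e6, 60e6, 700e6))
  ds <- inter_co_distances(ev, m, samples = c("a", "b", "c"))
  expect_equal(ds$d[sample == "a"]$d_bp, 600e6)
  expect_equal(nrow(ds$d[sample == "b"]), 0L)   # single event: no distance
  expect_equal(ds$d[sample == "c"]$d_bp, c(40e6, 640e6))
  expect_true(all(ds$d$L == 760e6))
  # distances per contributing pair = events - 1
  expect_equal(nrow(ds$d), sum(ds$counts$n_events - 1L))
  # chromatid intensity: 6 events over 3 samples
  expect_equal(ds$intensity$g_hat, 2)
})

test_that("distance histogram uses 100-Mbp classes and normalises", {
  m <- tiny_map(1, length = 760e6)
  ev <- data.table::data.table(sample = rep(letters[1:3], each = 2),
                               chrom = "tc1",
                               midpoint = c(0, 50e6, 100e6, 250e6,
                                            10e6, 760e6 - 1))
  ds <- inter_co_distances(ev, m)
  h <- distance_histogram(ds)
  expect_equal(sum(h$freq$freq), 1)
  expect_equal(h$freq$class[1], "<100")
  expect_equal(h$freq$class[8], ">700")
  expect_equal(h$freq$count[1], 1L)   # 50 Mbp
  expect_equal(h$freq$count[2], 1L)   # 150 Mbp
  expect_equal(h$freq$count[8], 1L)   # 750 Mbp

  all_small <- inter_co_distances(
    data.table::data.table(sample = "a", chrom = "tc1",
                           midpoint = c(10e6, 60e6)), m)
  expect_equal(distance_histogram(all_small)$freq$freq[1], 1)
  expect_error(distance_histogram(inter_co_distances(ev[0], m)), "empty")
})

test_that("no-interference simulations give a decaying unimodal distance histogram", {
  m <- default_genome_map(map_type = "uniform")
  ev <- simulate_true_events(m, meiosis_model(nu = 1), n = 300, seed = 130)
  ds <- inter_co_distances(ev, m)
  h <- distance_histogram(ds)
  expect_equal(which.max(h$freq$freq), 1L)
  expect_true(all(diff(h$freq$freq[1:4]) < 0))
})

test_that("the discrepancy statistic separates distributions", {
  set.seed(131)
  x <- stats::runif(300)
  expect_lt(sgrec:::.cvm2(x, x), 0.01)
  y_far <- stats::runif(300) + 0.5
  expect_gt(sgrec:::.cvm2(x, y_far), sgrec:::.cvm2(x, stats::runif(300)))
})

test_that("estimate_nu refuses degenerate inputs", {
  m <- tiny_map(1, length = 760e6)
  few <- inter_co_distances(
    data.table::data.table(sample = "a", chrom = "tc1",
                           midpoint = c(1e6, 2e6)), m)
  expect_error(estimate_nu(few), "too few")
  ev <- data.table::data.table(sample = rep(letters[1:12], each = 2),
                               chrom = "tc1",
                               midpoint = rep(c(1e6, 2e6), 12) +
                                 rep(1:12, each = 2) * 1e4)
  ds <- inter_co_distances(ev, m)
  expect_error(estimate_nu(ds, grid = c(-1, 2)), "grid")
  expect_error(estimate_nu(ds, grid = 3), "grid")
})

test_that("estimate_nu recovers the no-interference null and is reproducible", {
  m <- default_genome_map(map_type = "uniform")
  ev <- simulate_true_events(m, meiosis_model(nu = 1), n = 150, seed = 132)
  ds <- inter_co_distances(ev, m)
  fit <- estimate_nu(ds, replicates = 150, seed = 7)
  expect_gte(fit$nu, 0.5)
  expect_lte(fit$nu, 2)
  # common random numbers: bit-identical profile for the same seed
  fit2 <- estimate_nu(ds, replicates = 150, seed = 7)
  expect_identical(fit$profile, fit2$profile)
  # minimum of the profile is the estimate
  expect_equal(fit$profile[which.min(discrepancy)]$nu, fit$nu)
})

test_that("stronger simulated interference yields larger estimates", {
  m <- default_genome_map(map_type = "uniform")
  concordant <- 0L
  n_pairs <- 6L
  for (r in seq_len(n_pairs)) {
    e2 <- simulate_true_events(m, meiosis_model(nu = 2), 120, seed = 200 + r)
    e8 <- simulate_true_events(m, meiosis_model(nu = 8), 120, seed = 200 + r)
    f2 <- estimate_nu(inter_co_distances(e2, m), replicates = 120,
                      seed = 300 + r)
    f8 <- estimate_nu(inter_co_distances(e8, m), replicates = 120,
                      seed = 300 + r)
    concordant <- concordant + (f8$nu > f2$nu)
  }
  expect_gte(concordant, n_pairs - 1L)
})

test_that("class-split fits separate a two-pathway mixture and refuse empty classes", {
  m <- default_genome_map(map_type = "uniform")
  # 60/40 mixture of strongly and non-interfering processes
  ia <- simulate_true_events(m, meiosis_model(nu = 8, genetic_length = 0.9),
                             n = 250, seed = 140)
  ib <- simulate_true_events(m, meiosis_model(nu = 1, genetic_length = 0.6),
                             n = 160, seed = 141)
  ib[, sample := paste0("x", sample)]
  ev <- rbind(ia, ib)
  ds <- inter_co_distances(ev, m)
  fits <- class_split_fit(ds, replicates = 120, seed = 11)
  expect_lt(fits$near$nu, fits$far$nu)

  # far-only data: the near class must refuse, not silently fit
  far_only <- inter_co_distances(
    data.table::data.table(sample = rep(letters[1:12], each = 2),
                           chrom = "tc1",
                           midpoint = rep(c(50e6, 700e6), 12)),
    tiny_map(1, length = 760e6))
  expect_error(class_split_fit(far_only, replicates = 50, seed = 1),
               "near class")
})

test_that("successive crossover pairs are classified by chromosome arm", {
  m <- tiny_map(1, length = 760e6)
  ev <- data.table::data.table(
    sample = c("a", "a", "b", "b", "c", "c", "c"),
    chrom = "tc1",
    midpoint = c(30e6, 700e6, 30e6, 90e6, 400e6, 500e6, 700e6))
  sc <- co_position_scatter(ev, m)
  expect_equal(sc[sample == "a"]$quadrant, "opposite_arms")
  expect_equal(sc[sample == "b"]$quadrant, "same_arm_left")
  expect_equal(sc[sample == "c"]$quadrant, rep("same_arm_right", 2))
  expect_equal(sc[sample == "c"]$first, c(400e6, 500e6))

  none <- co_position_scatter(
    data.table::data.table(sample = "a", chrom = "tc1", midpoint = 1e6), m)
  expect_equal(nrow(none), 0L)
})
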