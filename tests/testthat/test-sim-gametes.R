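test_that("bundle renewal process has intensity 2/Morgan and is stationary", {
  expect_identical(simulate_bundle_crossovers(0, 1), numeric(0))
  expect_error(simulate_bundle_crossovers(2, 0), "positive")
  expect_error(simulate_bundle_crossovers(2, -1), "positive")
  expect_error(meiosis_model(nu = 0), "positive")

  set.seed(101)
  n <- 10000
  cnt <- lengths(simulate_chromatids(n, 2, 1, thin = FALSE))
  # Poisson limit at nu = 1: mean 4, se sqrt(4/n)
  expect_lt(abs(mean(cnt) - 4), 3 * sqrt(4 / n))

  # stationarity: same mean count in the two halves of the interval
  for (nu in c(0.5, 1, 5)) {
    pos <- simulate_chromatids(n, 2, nu, thin = FALSE)
    lo <- vapply(pos, function(p) sum(p < 1), 0)
    hi <- vapply(pos, function(p) sum(p >= 1), 0)
    se <- sqrt(stats::var(lo - hi) / n)
    expect_lt(abs(mean(lo) - mean(hi)), 3 * max(se, 1e-3))
  }
})

test_that("inter-event distances are exponential at nu = 1 and tighten with nu", {
  set.seed(102)
  # gaps taken far from the interval end are free of right-censoring
  uncensored_gaps <- function(nu) {
    b <- simulate_chromatids(2000, 20, nu, thin = FALSE)
    unlist(lapply(b, function(p) {
      d <- diff(p)
      d[p[-length(p)] < 10]
    }))
  }
  g1 <- uncensored_gaps(1)
  expect_gt(length(g1), 10000)
  expect_gt(stats::ks.test(g1, stats::pexp, rate = 2)$p.value, 0.001)
  g10 <- uncensored_gaps(10)
  # gamma gap variance shape/rate^2 = 1/(4 nu) decreases with nu
  expect_lt(stats::var(g10), stats::var(g1))
})

test_that("chromatid thinning halves intensity independently of position", {
  expect_identical(thin_to_chromatid(numeric(0)), numeric(0))
  set.seed(103)
  n <- 10000
  cnt <- lengths(simulate_chromatids(n, 2, 1, thin = TRUE))
  expect_lt(abs(mean(cnt) - 2), 3 * sqrt(2 / n))

  # retention indicator independent of event position
  ev <- unlist(simulate_chromatids(3000, 2, 1, thin = FALSE))
  keep <- stats::runif(length(ev)) < 0.5
  q <- cut(ev, stats::quantile(ev, 0:4 / 4), include.lowest = TRUE)
  expect_gt(stats::chisq.test(table(q, keep))$p.value, 0.001)
})

test_that("genetic-to-physical mapping is monotone and honours the map shape", {
  m <- tiny_map(1, length = 600e6, genetic_length = 1)
  expect_equal(genetic_to_physical(0.5, m, "tc1"), 300e6)
  expect_identical(genetic_to_physical(numeric(0), m, "tc1"), numeric(0))
  expect_error(genetic_to_physical(1.5, m, "tc1"), "outside")

  x <- sort(stats::runif(50))
  expect_true(all(diff(genetic_to_physical(x, m, "tc1")) > 0))

  # distal-elevated map starves the chromosome middle of crossovers
  md <- default_genome_map(map_type = "distal")
  set.seed(104)
  ev <- simulate_true_events(md, meiosis_model(nu = 1), n = 1500, seed = 104)
  L <- chrom_lengths(md)[ev$chrom]
  frac_mid <- mean(ev$midpoint > 0.3 * L & ev$midpoint < 0.7 * L)
  expect_lt(frac_mid, 0.15)
})

test_that("gametes alternate parental origin exactly at crossovers", {
  m <- tiny_map(1)
  set.seed(105)
  # force zero crossovers via zero genetic length
  g0 <- make_gamete(m, meiosis_model(nu = 1, genetic_length = 0))
  expect_length(g0$crossovers[["tc1"]], 0)
  ori <- gamete_origin(g0, "tc1", seq(1e6, 59e6, by = 1e6))
  expect_length(unique(ori), 1L)

  found <- FALSE
  for (i in 1:50) {
    g <- make_gamete(m, meiosis_model(nu = 1, genetic_length = 1))
    co <- g$crossovers[["tc1"]]
    if (length(co) >= 1) {
      found <- TRUE
      for (x in co) {
        expect_equal(abs(gamete_origin(g, "tc1", x + 1) -
                           gamete_origin(g, "tc1", x - 1)), 1L)
      }
      expect_identical(gamete_origin(g, "tc1", 0), g$start[["tc1"]])
    }
  }
  expect_true(found)
})

test_that("selection model hits the target transmission rate and decays with linkage", {
  m <- tiny_map(1, length = 60e6, genetic_length = 0.6)
  sel <- selection_model(data.frame(chrom = "tc1", pos = 10e6,
                                    p1_prob = 0.9))
  set.seed(106)
  n <- 4000
  at_locus <- linked <- integer(n)
  for (i in seq_len(n)) {
    g <- make_gamete(m, meiosis_model(nu = 1, genetic_length = 0.6), sel)
    at_locus[i] <- gamete_origin(g, "tc1", 10e6)
    linked[i] <- gamete_origin(g, "tc1", 40e6)   # 30 Mbp = 0.3 M away
  }
  f_locus <- mean(at_locus == 1L)
  se <- sqrt(0.9 * 0.1 / n)
  expect_lt(abs(f_locus - 0.9), 3 * se)
  f_link <- mean(linked == 1L)
  expect_gt(f_link, 0.55)   # distorted ...
  expect_lt(f_link, 0.85)   # ... but less than at the locus

  # no selection: Mendelian 1:1 at every position
  set.seed(107)
  ori <- vapply(seq_len(n), function(i)
    gamete_origin(make_gamete(m, meiosis_model(nu = 1, genetic_length = 0.6)),
                  "tc1", 30e6), 0L)
  expect_lt(abs(mean(ori == 1L) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("observation model is faithful at the extremes and binomial in between", {
  m <- tiny_map(1, spacing = 5e3)   # 12,000 markers
  set.seed(108)
  g <- make_gamete(m, meiosis_model(nu = 1, genetic_length = 0.6))
  truth <- gamete_origin(g, "tc1", m$markers$pos)

  full <- observe_gamete(g, m, observation_model(detect_prob = 1,
                                                 error_rate = 0))
  expect_equal(nrow(full), nrow(m$markers))
  expect_identical(full$call, truth)

  none <- observe_gamete(g, m, observation_model(detect_prob = 0))
  expect_equal(nrow(none), 0L)

  part <- observe_gamete(g, m, observation_model(detect_prob = 0.3,
                                                 error_rate = 0))
  frac <- nrow(part) / nrow(m$markers)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(m$markers)))
})

test_that("population VCF round-trips through the reader", {
  m <- tiny_map(2, spacing = 5e5)
  pop <- simulate_population(m, meiosis_model(nu = 1, genetic_length = 0.6),
                             observation_model(detect_prob = 0.4,
                                               error_rate = 0.02),
                             n = 12, seed = 109)
  vcf <- tempfile(fileext = ".vcf")
  write_population_vcf(pop, vcf)
  got <- read_calls(vcf, m, verbose = FALSE)
  want <- data.table::setorder(data.table::copy(pop$calls),
                               sample, chrom, pos)
  expect_identical(got$sample, want$sample)
  expect_identical(got$pos, want$pos)
  expect_identical(got$call, want$call)

  # header-only file (no samples) is accepted and yields an empty table
  v2 <- tempfile(fileext = ".vcf")
  empty <- data.table::data.table(sample = character(0),
                                  chrom = character(0),
                                  pos = numeric(0), call = integer(0))
  write_population_vcf(empty, v2, map = m, samples = character(0))
  expect_equal(nrow(read_calls(v2, m, verbose = FALSE)), 0L)
})

test_that("per-sample seeding makes populations reproducible", {
  m <- tiny_map(1)
  p1 <- simulate_population(m, n = 5, seed = 42)
  p2 <- simulate_population(m, n = 5, seed = 42)
  expect_identical(p1$calls, p2$calls)
  expect_identical(true_crossovers(p1), true_crossovers(p2))
  p3 <- simulate_population(m, n = 5, seed = 43)
  expect_false(identical(p1$calls, p3$calls))
})
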