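#' Meiosis model
#'
#' Parameters of crossover formation on a bivalent. Crossovers on the
#' four-chromatid bundle follow a stationary gamma renewal process with
#' shape `nu` and rate `2 * nu` events per Morgan, so the bundle intensity
#' is 2 events/Morgan and, after random 1/2-thinning to a single chromatid,
#' the chromatid carries on average `G` crossovers on a chromosome of
#' genetic length `G` Morgans. `nu = 1` corresponds to no interference
#' (Poisson placement); `nu > 1` to positive interference (more regular
#' spacing); `nu < 1` to negative interference.
#'
#' @param nu gamma shape parameter (interference strength), `> 0`.
#' @param genetic_length default genetic length per chromosome in Morgans,
#'   used when the genome map carries no genetic map of its own.
#' @param obligate_co if `TRUE`, chromatids with zero crossovers are
#'   resampled (off by default: a sizeable fraction of real chromatids
#'   carries no detectable crossover).
#' @return An object of class `meiosis_model`.
#' @export
meiosis_model <- function(nu = 3, genetic_length = 1.4, obligate_co = FALSE) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0)
    stop("nu must be a single positive number")
  if (genetic_length < 0) stop("genetic_length must be >= 0")
  structure(list(nu = nu, genetic_length = genetic_length,
                 obligate_co = isTRUE(obligate_co)),
            class = "meiosis_model")
}

#' Observation model for sparse genotype calls
#'
#' Emulates very low-coverage single-cell genotyping at the call level:
#' each marker is observed in a given sample with probability
#' `detect_prob`, and an observed call reports the wrong parental allele
#' with probability `error_rate`. With `sample_sd > 0` the per-sample
#' detection probability is itself drawn from a Beta distribution with
#' mean `detect_prob`, emulating coverage differences between cells.
#'
#' @param detect_prob probability that a marker is observed in a sample.
#' @param error_rate probability that an observed call is flipped.
#' @param sample_sd standard deviation of the per-sample detection
#'   probability (0 = identical coverage for all samples).
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(detect_prob = 0.1, error_rate = 0.01,
                              sample_sd = 0) {
  stopifnot(detect_prob >= 0, detect_prob <= 1,
            error_rate >= 0, error_rate <= 1, sample_sd >= 0)
  structure(list(detect_prob = detect_prob, error_rate = error_rate,
                 sample_sd = sample_sd),
            class = "observation_model")
}

#' Selection model (transmission bias)
#'
#' Loci under gametic/regeneration selection: at each locus the parent-1
#' allele is transmitted with the stated marginal probability. Implemented
#' by rejection sampling of whole gametes, so linked markers show a
#' distortion that decays with their recombination distance from the
#' selected locus - the mechanism that creates segregation distortion
#' regions in double-haploid-like populations.
#'
#' @param loci data.frame with columns `chrom`, `pos` (bp) and `p1_prob`
#'   (marginal transmission probability of the parent-1 allele, in
#'   `[0, 1]`; 0.5 = Mendelian).
#' @return An object of class `selection_model`, or `NULL` for no selection.
#' @export
selection_model <- function(loci = NULL) {
  if (is.null(loci) || nrow(loci) == 0L) return(NULL)
  loci <- as.data.frame(loci)
  stopifnot(all(c("chrom", "pos", "p1_prob") %in% names(loci)),
            all(loci$p1_prob >= 0 & loci$p1_prob <= 1))
  structure(list(loci = loci), class = "selection_model")
}

# cache of equilibrium-distribution inversion grids, keyed by nu
.eq_cache <- new.env(parent = emptyenv())

# Inverse CDF of the equilibrium (forward recurrence) distribution of
# Gamma(shape = nu, rate = 2 nu). Closed form of the CDF:
#   F_e(x) = 2 x (1 - F_nu(x)) + F_{nu+1}(x)
# inverted numerically once per nu on a grid, then looked up.
.eq_first_event <- function(n, nu) {
  key <- sprintf("%.12g", nu)
  g <- .eq_cache[[key]]
  if (is.null(g)) {
    rate <- 2 * nu
    xmax <- stats::qgamma(1 - 1e-12, nu + 1, rate) + 2
    xg <- seq(0, xmax, length.out = 4096L)
    Fe <- 2 * xg * stats::pgamma(xg, nu, rate, lower.tail = FALSE) +
      stats::pgamma(xg, nu + 1, rate)
    Fe <- cummax(Fe)  # guard against numerical non-monotonicity
    keep <- !duplicated(Fe)
    g <- list(x = xg[keep], F = Fe[keep])
    .eq_cache[[key]] <- g
  }
  stats::approx(g$F, g$x, xout = stats::runif(n), rule = 2)$y
}

#' Simulate crossover positions on the four-chromatid bundle
#'
#' Draws one realisation of the stationary gamma renewal process on
#' `[0, G]` Morgans: inter-event distances are i.i.d.
#' Gamma(shape = `nu`, rate = `2 nu`), and the first event is drawn from
#' the equilibrium forward-recurrence distribution so that event counts
#' are stationary along the chromosome.
#'
#' @param genetic_length interval length `G` in Morgans.
#' @param nu gamma shape (interference strength), `> 0`.
#' @return Sorted numeric vector of event positions in Morgans (possibly
#'   empty). Uses the R random number generator; seed with [set.seed()].
#' @export
simulate_bundle_crossovers <- function(genetic_length, nu) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0)
    stop("nu must be a single positive number")
  if (genetic_length < 0) stop("genetic_length must be >= 0")
  .sim_chromatid_batch(1L, genetic_length, nu, thin = FALSE)[[1L]]
}

#' Thin bundle crossovers to a single chromatid
#'
#' Each crossover of the bundle involves the sampled chromatid with
#' probability 1/2, independently (no chromatid interference), halving the
#' intensity from 2 to 1 event/Morgan.
#'
#' @param bundle_events sorted numeric vector of bundle event positions.
#' @return Subset of `bundle_events` retained on the chromatid.
#' @export
thin_to_chromatid <- function(bundle_events) {
  if (length(bundle_events) == 0L) return(bundle_events)
  bundle_events[stats::runif(length(bundle_events)) < 0.5]
}

#' Simulate many chromatids at once
#'
#' Vectorised generation of `n` independent chromatids (or bundles, with
#' `thin = FALSE`) under the stationary gamma renewal model.
#'
#' @param n number of chromatids.
#' @param genetic_length interval length in Morgans.
#' @param nu gamma shape, `> 0`.
#' @param thin if `TRUE` (default) apply 1/2-thinning to a chromatid.
#' @return List of `n` sorted numeric vectors of positions in Morgans.
#' @export
simulate_chromatids <- function(n, genetic_length, nu, thin = TRUE) {
  if (nu <= 0) stop("nu must be positive")
  .sim_chromatid_batch(as.integer(n), genetic_length, nu, thin = thin)
}

.sim_chromatid_batch <- function(n, G, nu, thin = TRUE) {
  if (n == 0L) return(list())
  if (G <= 0) return(rep(list(numeric(0)), n))
  rate <- 2 * nu
  acc <- .eq_first_event(n, nu)
  cols <- list(acc)
  while (any(acc <= G)) {
    acc <- acc + stats::rgamma(n, shape = nu, rate = rate)
    cols[[length(cols) + 1L]] <- acc
  }
  P <- do.call(cbind, cols)
  keep <- P <= G
  if (thin)
    keep <- keep & (stats::runif(length(P)) < 0.5)
  rows <- rep.int(seq_len(n), ncol(P))
  sel <- which(keep)  # column-major: within-row order is increasing
  unname(split(P[sel], factor(rows[sel], levels = seq_len(n))))
}

#' Map genetic positions to physical positions
#'
#' Applies the chromosome's monotone piecewise-linear genetic map in the
#' physical direction: genetic position (Morgans) to physical position (bp).
#'
#' @param positions numeric vector of genetic positions in `[0, G]`.
#' @param map a [genome_map()] with a genetic map for `chrom`.
#' @param chrom chromosome name.
#' @return Numeric vector of physical positions in bp (strictly increasing
#'   for strictly increasing input).
#' @export
genetic_to_physical <- function(positions, map, chrom) {
  if (length(positions) == 0L) return(numeric(0))
  gmc <- map$genetic_map[[chrom]]
  if (is.null(gmc)) stop("no genetic map for chromosome ", chrom)
  G <- utils::tail(gmc$gen, 1)
  if (any(positions < 0 | positions > G))
    stop("genetic positions outside [0, G] on ", chrom)
  stats::approx(gmc$gen, gmc$phys, xout = positions, ties = "ordered")$y
}

.resolve_genetic <- function(map, meiosis) {
  # per-chromosome genetic maps: from the genome map if present, else a
  # uniform map with the meiosis model's genetic length
  chroms <- map$chromosomes$chrom
  gm <- map$genetic_map
  if (is.null(gm)) gm <- list()
  for (cc in chroms) {
    if (is.null(gm[[cc]]))
      gm[[cc]] <- uniform_genetic_map(chrom_lengths(map)[[cc]],
                                      meiosis$genetic_length)
  }
  gm[chroms]
}

#' Simulate one gamete
#'
#' Draws crossover positions per chromosome (gamma renewal bundle,
#' 1/2-thinning, genetic-to-physical mapping), a random starting parent,
#' and applies transmission bias by rejection sampling: gametes carrying
#' the disfavoured allele at a selection locus are rejected with the
#' probability that makes the marginal transmission rate equal the locus's
#' `p1_prob`.
#'
#' @param map a [genome_map()].
#' @param meiosis a [meiosis_model()].
#' @param selection a [selection_model()] or `NULL`.
#' @return An object of class `gamete`: per-chromosome crossover positions
#'   (bp, strictly increasing) and starting parent (1 or 2).
#' @export
make_gamete <- function(map, meiosis = meiosis_model(), selection = NULL) {
  gm <- .resolve_genetic(map, meiosis)
  chroms <- map$chromosomes$chrom
  loci <- if (!is.null(selection)) selection$loci else NULL
  repeat {
    co <- vector("list", length(chroms))
    names(co) <- chroms
    start <- stats::setNames(sample(1:2, length(chroms), replace = TRUE),
                             chroms)
    for (i in seq_along(chroms)) {
      cc <- chroms[i]
      G <- utils::tail(gm[[cc]]$gen, 1)
      repeat {
        ev <- .sim_chromatid_batch(1L, G, meiosis$nu)[[1L]]
        if (!meiosis$obligate_co || length(ev) > 0L) break
      }
      co[[cc]] <- if (length(ev))
        stats::approx(gm[[cc]]$gen, gm[[cc]]$phys, xout = ev,
                      ties = "ordered")$y
      else numeric(0)
    }
    g <- structure(list(crossovers = co, start = start), class = "gamete")
    if (is.null(loci)) return(g)
    acc <- 1
    for (j in seq_len(nrow(loci))) {
      o <- gamete_origin(g, loci$chrom[j], loci$pos[j])
      p <- loci$p1_prob[j]
      a <- if (p >= 0.5) {
        if (o == 1L) 1 else (1 - p) / max(p, 1e-12)
      } else {
        if (o == 2L) 1 else p / max(1 - p, 1e-12)
      }
      acc <- acc * a
    }
    if (stats::runif(1) < acc) return(g)
  }
}

#' Parental origin of a gamete at given positions
#'
#' @param gamete a [make_gamete()] result.
#' @param chrom chromosome name.
#' @param pos numeric vector of physical positions (bp).
#' @return Integer vector of parental origins (1 or 2): the starting parent
#'   toggled at each crossover.
#' @export
gamete_origin <- function(gamete, chrom, pos) {
  co <- gamete$crossovers[[chrom]]
  s <- gamete$start[[chrom]]
  n_before <- findInterval(pos, co)
  as.integer((s - 1L + n_before) %% 2L + 1L)
}

#' Observe a gamete through the sparse noisy genotyping model
#'
#' @param gamete a [make_gamete()] result.
#' @param map a [genome_map()] (its marker table defines the assayable sites).
#' @param obs an [observation_model()].
#' @return data.table with columns `chrom`, `pos`, `call` (1 = parent-1
#'   allele, 2 = parent-2 allele) for the observed markers only.
#' @export
observe_gamete <- function(gamete, map, obs = observation_model()) {
  mk <- map$markers
  dp <- obs$detect_prob
  if (obs$sample_sd > 0) {
    # Beta with mean detect_prob and sd sample_sd (clamped to feasible range)
    v <- min(obs$sample_sd^2, dp * (1 - dp) * 0.99)
    if (v > 0) {
      k <- dp * (1 - dp) / v - 1
      dp <- stats::rbeta(1, dp * k, (1 - dp) * k)
    }
  }
  seen <- stats::runif(nrow(mk)) < dp
  if (!any(seen))
    return(data.table::data.table(chrom = character(0), pos = numeric(0),
                                  call = integer(0)))
  mk <- mk[seen, , drop = FALSE]
  call <- integer(nrow(mk))
  for (cc in unique(mk$chrom)) {
    idx <- mk$chrom == cc
    call[idx] <- gamete_origin(gamete, cc, mk$pos[idx])
  }
  flip <- stats::runif(length(call)) < obs$error_rate
  call[flip] <- 3L - call[flip]
  data.table::data.table(chrom = mk$chrom, pos = mk$pos, call = call)
}

.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + i * 104729) %%
               2147483647)
}

#' Simulate a gamete or DH-like population
#'
#' Generates `n` gametes with known ground truth and their sparse noisy
#' genotype observations. Each sample uses an RNG stream derived from
#' `seed` and the sample index, so results are reproducible regardless of
#' sample ordering.
#'
#' @param map a [genome_map()].
#' @param meiosis a [meiosis_model()].
#' @param obs an [observation_model()].
#' @param selection a [selection_model()] or `NULL`.
#' @param n number of samples.
#' @param seed integer seed.
#' @param prefix sample-name prefix.
#' @return An object of class `gamete_population`: `samples` (ids),
#'   `truth` (list of gametes), `calls` (data.table of sample, chrom, pos,
#'   call), and the models used.
#' @export
simulate_population <- function(map, meiosis = meiosis_model(),
                                obs = observation_model(),
                                selection = NULL, n = 40, seed = 1,
                                prefix = "S") {
  samples <- sprintf("%s%03d", prefix, seq_len(n))
  truth <- vector("list", n)
  names(truth) <- samples
  calls <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.derive_seed(seed, i))
    g <- make_gamete(map, meiosis, selection)
    truth[[i]] <- g
    ci <- observe_gamete(g, map, obs)
    if (nrow(ci)) ci[, sample := samples[i]]
    calls[[i]] <- ci
  }
  calls <- data.table::rbindlist(calls, use.names = TRUE, fill = TRUE)
  structure(list(samples = samples, truth = truth, calls = calls,
                 map = map, meiosis = meiosis, obs = obs,
                 selection = selection, seed = seed),
            class = "gamete_population")
}

#' @export
print.gamete_population <- function(x, ...) {
  cat("gamete_population:", length(x$samples), "samples,",
      nrow(x$calls), "genotype calls\n")
  invisible(x)
}

#' True crossover table of a simulated population
#'
#' @param pop a [simulate_population()] result.
#' @return data.table with columns `sample`, `chrom`, `midpoint` (true
#'   crossover position in bp; named `midpoint` so the table plugs
#'   directly into the event-based analyses).
#' @export
true_crossovers <- function(pop) {
  out <- list()
  for (s in pop$samples) {
    g <- pop$truth[[s]]
    for (cc in names(g$crossovers)) {
      co <- g$crossovers[[cc]]
      if (length(co))
        out[[length(out) + 1L]] <-
          data.table::data.table(sample = s, chrom = cc, midpoint = co)
    }
  }
  if (!length(out))
    return(data.table::data.table(sample = character(0),
                                  chrom = character(0),
                                  midpoint = numeric(0)))
  data.table::rbindlist(out)
}

#' Simulate true crossover events without the observation layer
#'
#' Fast path used for interference studies: simulates `n` chromatids per
#' chromosome directly (gamma renewal bundle + thinning + physical
#' mapping) and returns their true crossover positions as an event table.
#'
#' @param map a [genome_map()] with genetic maps.
#' @param meiosis a [meiosis_model()].
#' @param n number of gametes.
#' @param seed integer seed.
#' @return data.table with columns `sample`, `chrom`, `midpoint` (bp).
#' @export
simulate_true_events <- function(map, meiosis = meiosis_model(), n = 100,
                                 seed = 1) {
  set.seed(seed)
  gm <- .resolve_genetic(map, meiosis)
  samples <- sprintf("S%04d", seq_len(n))
  out <- list()
  for (cc in map$chromosomes$chrom) {
    G <- utils::tail(gm[[cc]]$gen, 1)
    sims <- .sim_chromatid_batch(n, G, meiosis$nu)
    len <- lengths(sims)
    if (sum(len) == 0L) next
    gpos <- unlist(sims, use.names = FALSE)
    ppos <- stats::approx(gm[[cc]]$gen, gm[[cc]]$phys, xout = gpos,
                          ties = "ordered")$y
    out[[length(out) + 1L]] <- data.table::data.table(
      sample = rep(samples, len), chrom = cc, midpoint = ppos)
  }
  if (!length(out))
    return(data.table::data.table(sample = character(0),
                                  chrom = character(0),
                                  midpoint = numeric(0)))
  data.table::rbindlist(out)
}

#' Write the true-crossover table to TSV
#'
#' @param pop a [simulate_population()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(pop, path) {
  data.table::fwrite(true_crossovers(pop), path, sep = "\t")
  invisible(path)
}
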