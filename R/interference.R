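#' Inter-crossover distances
#'
#' Physical distances between adjacent crossover events within each
#' sample x chromosome carrying at least `min_events` events, pooled
#' across chromosomes. The returned object also records the per-
#' chromosome event counts of the contributing samples and the genome
#' map - both are needed to fit the gamma interference model.
#'
#' @param events event table with `sample`, `chrom`, `midpoint` columns.
#' @param map a [genome_map()].
#' @param min_events minimum events per sample/chromosome (default 2, the
#'   smallest number yielding a distance).
#' @param samples optional character vector of all sample ids in the
#'   population (samples without events included). Used to estimate the
#'   per-chromosome crossover intensity - the mean event count per
#'   chromatid, which for a stationary renewal chromatid equals the
#'   genetic length in Morgans whatever the interference strength. If
#'   omitted, the samples present in `events` are used (a slight
#'   underestimate when some samples carry no event anywhere).
#' @return Object of class `co_distances`: `d` (data.table with `sample`,
#'   `chrom`, `d_bp`, `L`), `counts` (data.table with `sample`, `chrom`,
#'   `n_events` for the contributing >= `min_events` pairs), `intensity`
#'   (data.table with `chrom`, `g_hat`: mean events/chromatid), and `map`.
#' @export
inter_co_distances <- function(events, map, min_events = 2,
                               samples = NULL) {
  stopifnot(min_events >= 2)
  ev <- data.table::as.data.table(events)
  lens <- chrom_lengths(map)
  if (is.null(samples)) samples <- unique(ev$sample)
  n_samp <- max(length(samples), 1L)
  if (nrow(ev)) {
    data.table::setorder(ev, sample, chrom, midpoint)
    counts <- ev[, .N, by = .(sample, chrom)][N >= min_events]
    data.table::setnames(counts, "N", "n_events")
    d <- ev[, if (.N >= min_events) .(d_bp = diff(midpoint)) else NULL,
            by = .(sample, chrom)]
    intensity <- ev[, .(g_hat = .N / n_samp), by = chrom]
  } else {
    counts <- data.table::data.table(sample = character(0),
                                     chrom = character(0),
                                     n_events = integer(0))
    d <- data.table::data.table(sample = character(0), chrom = character(0),
                                d_bp = numeric(0))
    intensity <- data.table::data.table(chrom = character(0),
                                        g_hat = numeric(0))
  }
  d[, L := lens[chrom]]
  structure(list(d = d, counts = counts, intensity = intensity,
                 n_samples = n_samp, map = map),
            class = "co_distances")
}

#' @export
print.co_distances <- function(x, ...) {
  cat("co_distances:", nrow(x$d), "distances from", nrow(x$counts),
      "sample x chromosome pairs\n")
  invisible(x)
}

#' Inter-crossover distance histogram
#'
#' Relative frequencies of inter-crossover distances in fixed-width
#' classes (default 100 Mbp, from `<100` up to `>700` Mbp), overall and
#' per chromosome (the per-chromosome spread yields the error bars of the
#' classic distance-class figure).
#'
#' @param x a [inter_co_distances()] object.
#' @param class_width class width in bp.
#' @param max_class lower edge of the open top class in bp.
#' @return List with `freq` (data.table: `class`, `count`, `freq`),
#'   `per_chrom` (frequency matrix classes x chromosomes), `n`.
#' @export
distance_histogram <- function(x, class_width = 100e6, max_class = 700e6) {
  d <- x$d
  if (nrow(d) == 0L) stop("empty distance set")
  breaks <- c(seq(0, max_class, by = class_width), Inf)
  mb <- class_width / 1e6
  lab <- c(sprintf("<%d", as.integer(mb)),
           sprintf("%d-%d", as.integer(seq(mb, max_class / 1e6 - mb, mb)),
                   as.integer(seq(2 * mb, max_class / 1e6, mb))),
           sprintf(">%d", as.integer(max_class / 1e6)))
  cl <- cut(d$d_bp, breaks = breaks, labels = lab, right = FALSE)
  cnt <- table(cl)
  chroms <- sort(unique(d$chrom))
  per_chrom <- vapply(chroms, function(cc) {
    tb <- table(cl[d$chrom == cc])
    as.numeric(tb) / max(sum(tb), 1L)
  }, numeric(length(lab)))
  rownames(per_chrom) <- lab
  list(freq = data.table::data.table(class = lab, count = as.integer(cnt),
                                     freq = as.numeric(cnt) / sum(cnt)),
       per_chrom = per_chrom, n = nrow(d))
}

# two-sample Cramer-von Mises statistic (Anderson's rank formula)
.cvm2 <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  rx <- sort(r[seq_len(n)])
  ry <- sort(r[n + seq_len(m)])
  U <- n * sum((rx - seq_len(n))^2) + m * sum((ry - seq_len(m))^2)
  U / (as.numeric(n) * m * (n + m)) - (4 * as.numeric(n) * m - 1) /
    (6 * (n + m))
}

# two-sample Kolmogorov-Smirnov statistic
.ks2 <- function(x, y) {
  as.numeric(stats::ks.test(x, y)$statistic)
}

# genetic length (Morgans) of an interval such that a Poisson chromatid,
# conditioned on >= min_events events, has the given mean event count
.g_from_truncated_mean <- function(mean_k, min_events = 2) {
  target <- max(mean_k, min_events + 0.01)
  f <- function(G) {
    p0 <- exp(-G); p1 <- G * exp(-G)
    (G - p1) / max(1 - p0 - p1, 1e-12) - target
  }
  if (f(1e-3) > 0) return(1e-3)
  stats::uniroot(f, c(1e-3, 50), tol = 1e-6)$root
}

# simulate chromatids with >= 2 events whose count distribution matches
# `target_counts`; returns a list of genetic-position vectors
.sim_conditioned <- function(target_counts, G, nu, max_batches = 25L) {
  need <- table(target_counts)
  ks <- as.integer(names(need))
  got <- stats::setNames(vector("list", length(ks)), names(need))
  pool_extra <- list()   # fallback: any chromatid with >= 2 events
  n_total <- length(target_counts)
  for (b in seq_len(max_batches)) {
    miss <- vapply(names(need), function(k)
      need[[k]] - length(got[[k]]), 0)
    if (all(miss <= 0)) break
    batch <- .sim_chromatid_batch(max(4L * n_total, 64L), G, nu)
    len <- lengths(batch)
    for (k in names(need)) {
      if (miss[[k]] <= 0) next
      hit <- batch[len == as.integer(k)]
      got[[k]] <- c(got[[k]], hit)
    }
    pool_extra <- c(pool_extra, batch[len >= 2L])
    if (length(pool_extra) > 50L * n_total) pool_extra <-
        pool_extra[seq_len(50L * n_total)]
  }
  out <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    k <- as.character(target_counts[i])
    if (length(got[[k]])) {
      out[[i]] <- got[[k]][[1L]]
      got[[k]] <- got[[k]][-1L]
    } else if (length(pool_extra)) {
      # requested count never produced at this nu; nearest available
      out[[i]] <- pool_extra[[sample.int(length(pool_extra), 1L)]]
    } else {
      out[[i]] <- numeric(0)
    }
  }
  out[lengths(out) >= 2L]
}

#' Estimate crossover interference strength (gamma shape nu)
#'
#' Fits the stationary gamma renewal model by simulation: for every
#' candidate `nu` on a grid, chromatids are simulated per chromosome with
#' the chromosome's coordinate map and conditioned on the observed
#' per-chromosome event-count distribution (isolating interference from
#' crossover intensity), their inter-crossover distances are pooled, and
#' the discrepancy between observed and simulated distance distributions
#' is measured (Cramer-von Mises by default). The estimate is the grid
#' argmin; ties break toward smaller `nu`. Distances are compared on
#' chromosome-normalized coordinates (`d / L`) so chromosomes of
#' different lengths pool coherently.
#'
#' The same derived RNG stream is replayed at every grid point (common
#' random numbers), so the discrepancy profile is smooth and bit-for-bit
#' reproducible given `seed`.
#'
#' @param x a [inter_co_distances()] object.
#' @param grid candidate `nu` values (default 0.5 to 12 by 0.25).
#' @param replicates total number of simulated chromatids per grid point
#'   (allocated across chromosomes proportionally to the data).
#' @param seed integer seed for the simulation streams.
#' @param statistic `"cvm"` (default) or `"ks"`.
#' @param d_min,d_max restrict the comparison to observed and simulated
#'   distances in `(d_min, d_max]` bp (used by [class_split_fit()]).
#' @param min_distances refuse to fit with fewer observed distances.
#' @return Object of class `gamma_fit`: `nu` (estimate), `profile`
#'   (data.table of `nu`, `discrepancy`), `n_distances`, `settings`.
#' @export
estimate_nu <- function(x, grid = seq(0.5, 12, by = 0.25),
                        replicates = 1000, seed = 1,
                        statistic = c("cvm", "ks"),
                        d_min = 0, d_max = Inf, min_distances = 10) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(x, "co_distances"))
  if (length(grid) < 2L || any(grid <= 0))
    stop("grid must contain at least two positive nu values")
  grid <- sort(grid)
  dsel <- x$d[d_bp > d_min & d_bp <= d_max]
  if (nrow(dsel) < min_distances)
    stop("too few inter-crossover distances (", nrow(dsel), " < ",
         min_distances, ") for a gamma fit")
  obs <- dsel$d_bp / dsel$L
  lens <- chrom_lengths(x$map)
  per_chrom <- split(x$counts$n_events, x$counts$chrom)
  n_tot <- sum(lengths(per_chrom))
  gm <- x$map$genetic_map
  stat_fun <- if (statistic == "cvm") .cvm2 else .ks2
  g_hat <- stats::setNames(x$intensity$g_hat, x$intensity$chrom)
  chrom_plan <- lapply(names(per_chrom), function(cc) {
    ks <- per_chrom[[cc]]
    # chromatid intensity estimates the genetic length unbiasedly for any
    # nu; fall back to a truncated-count inversion if unavailable
    G <- if (!is.na(g_hat[cc])) max(g_hat[[cc]], 0.2)
    else .g_from_truncated_mean(mean(ks))
    list(chrom = cc,
         n_sim = max(8L, ceiling(replicates * length(ks) / n_tot)),
         counts = ks, G = G, L = lens[[cc]],
         gmap = if (!is.null(gm)) gm[[cc]] else NULL)
  })
  prof <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    nu <- grid[gi]
    set.seed(.derive_seed(seed, 1L))  # common random numbers across grid
    sim_d <- list()
    for (pl in chrom_plan) {
      target <- sample(pl$counts, pl$n_sim, replace = TRUE)
      sims <- .sim_conditioned(target, pl$G, nu)
      if (!length(sims)) next
      len <- lengths(sims)
      gpos <- unlist(sims, use.names = FALSE)
      frac <- if (!is.null(pl$gmap))
        stats::approx(pl$gmap$gen, pl$gmap$phys, xout = gpos,
                      ties = "ordered")$y / pl$L
      else gpos / pl$G
      dd <- unlist(lapply(split(frac, rep(seq_along(len), len)), diff),
                   use.names = FALSE)
      dbp <- dd * pl$L
      sim_d[[length(sim_d) + 1L]] <- dd[dbp > d_min & dbp <= d_max]
    }
    sim_d <- unlist(sim_d, use.names = FALSE)
    prof[gi] <- if (length(sim_d) < 5L) Inf else stat_fun(obs, sim_d)
  }
  est <- grid[which.min(prof)]
  structure(list(nu = est,
                 profile = data.table::data.table(nu = grid,
                                                  discrepancy = prof),
                 n_distances = length(obs),
                 settings = list(grid = range(grid),
                                 grid_step = if (length(grid) > 1)
                                   min(diff(grid)) else NA,
                                 replicates = replicates, seed = seed,
                                 statistic = statistic,
                                 d_min = d_min, d_max = d_max)),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat("gamma_fit: nu =", x$nu, "(", x$n_distances, "distances,",
      x$settings$statistic, "discrepancy )\n")
  invisible(x)
}

#' Separate gamma fits for near and far inter-crossover distances
#'
#' Splits the observed distances into a near class (`< near` bp) and a far
#' class (`> far` bp) and fits the interference model to each class
#' separately, mirroring the two-pathway (class I / class II crossover)
#' interpretation of a bimodal distance distribution: a weakly
#' interfering near class and a strongly interfering far class.
#'
#' @param x a [inter_co_distances()] object.
#' @param near upper bound of the near class in bp (default 100 Mbp).
#' @param far lower bound of the far class in bp (default 400 Mbp).
#' @param min_distances minimum observed distances per class; fewer is an
#'   error, never a silent fit.
#' @param ... passed on to [estimate_nu()].
#' @return List with elements `near` and `far`, both `gamma_fit`.
#' @export
class_split_fit <- function(x, near = 100e6, far = 400e6,
                            min_distances = 10, ...) {
  n_near <- sum(x$d$d_bp < near)
  n_far <- sum(x$d$d_bp > far)
  if (n_near < min_distances)
    stop("near class holds only ", n_near, " distances (need ",
         min_distances, ")")
  if (n_far < min_distances)
    stop("far class holds only ", n_far, " distances (need ",
         min_distances, ")")
  list(near = estimate_nu(x, d_min = 0, d_max = near,
                          min_distances = min_distances, ...),
       far = estimate_nu(x, d_min = far, d_max = Inf,
                         min_distances = min_distances, ...))
}

#' Paired positions of successive crossovers
#'
#' For every sample x chromosome with at least two events, returns the
#' physical positions of each adjacent event pair together with a
#' quadrant classification relative to the chromosome midpoint:
#' `"same_arm_left"` (both events proximal of the midpoint),
#' `"same_arm_right"`, or `"opposite_arms"`. Plotted first-vs-second,
#' opposite-arm pairs fall in the off-diagonal quadrant (strong physical
#' interference), same-arm pairs hug the diagonal corners.
#'
#' @param events event table with `sample`, `chrom`, `midpoint`.
#' @param map a [genome_map()].
#' @return data.table with `sample`, `chrom`, `first`, `second`,
#'   `quadrant` (empty if no sample has two events).
#' @export
co_position_scatter <- function(events, map) {
  ev <- data.table::as.data.table(events)
  lens <- chrom_lengths(map)
  if (!nrow(ev))
    return(data.table::data.table(sample = character(0),
                                  chrom = character(0), first = numeric(0),
                                  second = numeric(0),
                                  quadrant = character(0)))
  data.table::setorder(ev, sample, chrom, midpoint)
  pairs <- ev[, if (.N >= 2L) .(first = midpoint[-.N], second = midpoint[-1L])
              else NULL,
              by = .(sample, chrom)]
  if (!nrow(pairs)) {
    pairs[, `:=`(first = numeric(0), second = numeric(0),
                 quadrant = character(0))]
    return(pairs[])
  }
  mid <- lens[pairs$chrom] / 2
  pairs[, quadrant := data.table::fifelse(
    first < mid & second < mid, "same_arm_left",
    data.table::fifelse(first >= mid & second >= mid, "same_arm_right",
                        "opposite_arms"))]
  pairs[]
}
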