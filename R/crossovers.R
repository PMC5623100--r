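#' Per-bin singleton-flip (double-crossover motif) rate
#'
#' For every bin, the fraction of samples in which the bin's call differs
#' from both nearest non-missing flanking calls while those flanks agree
#' with each other - the `0 -> 2 -> 0` / `2 -> 0 -> 2` motif, with missing
#' bins bridged. A high rate marks a genotyping-error-prone bin: a real
#' double crossover within ~2 bins of a single marker bin is possible in
#' one sample but not recurrently across samples.
#'
#' @param gm a `geno_matrix` (at least 2 samples).
#' @return data.table with `chrom`, `start`, `end`, `n_flips`, `flip_rate`.
#' @export
singleton_flip_rate <- function(gm) {
  if (length(gm$samples) < 2L)
    stop("at least 2 samples are required to estimate flip rates")
  nb <- nrow(gm$bins)
  flips <- integer(nb)
  chrom_idx <- split(seq_len(nb), gm$bins$chrom)
  for (s in seq_along(gm$samples)) {
    v <- gm$geno[, s]
    for (rows in chrom_idx) {
      idx <- rows[!is.na(v[rows])]
      k <- length(idx)
      if (k < 3L) next
      val <- v[idx]
      j <- which(val[-c(1L, k)] != val[-c(k - 1L, k)] &
                   val[-c(1L, 2L)] == val[-c(k - 1L, k)]) + 1L
      flips[idx[j]] <- flips[idx[j]] + 1L
    }
  }
  data.table::data.table(chrom = gm$bins$chrom, start = gm$bins$start,
                         end = gm$bins$end, n_flips = flips,
                         flip_rate = flips / length(gm$samples))
}

#' Curate error-prone bins
#'
#' Masks (sets to missing in all samples) bins whose singleton-flip rate
#' exceeds `max_flip_rate`, recomputing rates until no further bin exceeds
#' the threshold, so the operation is idempotent.
#'
#' @param gm a `geno_matrix`.
#' @param max_flip_rate flip-rate threshold above which a bin is masked.
#' @return List with `gm` (curated matrix) and `report` (data.table of
#'   per-bin flip rates at first pass, with a `removed` flag and the
#'   threshold as attribute).
#' @export
curate <- function(gm, max_flip_rate = 0.1) {
  report <- singleton_flip_rate(gm)
  removed <- rep(FALSE, nrow(report))
  cur <- gm
  rates <- report$flip_rate
  repeat {
    bad <- which(rates > max_flip_rate & !removed)
    if (!length(bad)) break
    removed[bad] <- TRUE
    cur$geno[bad, ] <- NA_integer_
    rates <- singleton_flip_rate(cur)$flip_rate
  }
  report[, removed := removed]
  data.table::setattr(report, "max_flip_rate", max_flip_rate)
  list(gm = cur, report = report)
}

.events_vector <- function(v, starts, ends) {
  idx <- which(!is.na(v))
  if (length(idx) < 2L) return(NULL)
  val <- v[idx]
  chg <- which(diff(val) != 0)
  if (!length(chg)) return(NULL)
  li <- idx[chg]
  ri <- idx[chg + 1L]
  left <- ends[li]          # last bp (1-based) of the preceding bin
  right <- starts[ri] + 1   # first bp (1-based) of the following bin
  data.table::data.table(left = left, right = right,
                         midpoint = (left + right) / 2,
                         from_code = val[chg], to_code = val[chg + 1L])
}

#' Detect crossover events in a genotype matrix
#'
#' Scans the informative (non-missing) bins of each sample x chromosome in
#' order and emits one event per adjacent pair of informative bins with
#' different parental codes. Missing bins are bridged, never used as
#' boundaries: a crossover is only called with an informative bin on both
#' sides. Event boundaries are the inner edges of the flanking informative
#' bins (1-based bp); the reported position is the interval midpoint.
#'
#' With `mask_singletons = TRUE`, lone informative bins that disagree
#' with both agreeing informative neighbours (the per-sample
#' double-crossover motif) are treated as missing before the scan. This
#' suppresses the spurious event pairs that isolated genotyping errors
#' create in very sparse data, at the price of also hiding any real
#' double crossover confined to a single bin; the default (`FALSE`)
#' reports every parental-origin transition as-is.
#'
#' @param gm a `geno_matrix` (typically curated, see [curate()]).
#' @param mask_singletons drop per-sample singleton flips before scanning.
#' @return data.table with columns `sample`, `chrom`, `left`, `right`,
#'   `midpoint`, `from_code`, `to_code`, ordered along each chromosome.
#' @export
detect_events <- function(gm, mask_singletons = FALSE) {
  nb <- nrow(gm$bins)
  chrom_idx <- split(seq_len(nb), gm$bins$chrom)
  out <- list()
  for (s in seq_along(gm$samples)) {
    v <- gm$geno[, s]
    for (cc in names(chrom_idx)) {
      rows <- chrom_idx[[cc]]
      vv <- v[rows]
      if (mask_singletons) {
        idx <- which(!is.na(vv))
        k <- length(idx)
        if (k >= 3L) {
          val <- vv[idx]
          j <- which(val[-c(1L, k)] != val[-c(k - 1L, k)] &
                       val[-c(1L, 2L)] == val[-c(k - 1L, k)]) + 1L
          vv[idx[j]] <- NA_integer_
        }
      }
      ev <- .events_vector(vv, gm$bins$start[rows], gm$bins$end[rows])
      if (!is.null(ev)) {
        ev[, `:=`(sample = gm$samples[s], chrom = cc)]
        out[[length(out) + 1L]] <- ev
      }
    }
  }
  if (!length(out))
    return(data.table::data.table(sample = character(0), chrom = character(0),
                                  left = numeric(0), right = numeric(0),
                                  midpoint = numeric(0),
                                  from_code = integer(0),
                                  to_code = integer(0)))
  ev <- data.table::rbindlist(out)
  data.table::setcolorder(ev, c("sample", "chrom", "left", "right",
                                "midpoint", "from_code", "to_code"))
  data.table::setorder(ev, sample, chrom, midpoint)
  ev
}

#' Event-count summary per chromosome and per sample
#'
#' Tabulates, per chromosome and pooled, the relative frequency of samples
#' carrying 0, 1, 2, ... crossover events, plus population totals and the
#' per-gamete mean with its standard error.
#'
#' @param events event table from [detect_events()] (or a true-crossover
#'   table with `sample`, `chrom`, `midpoint`).
#' @param samples character vector of all sample ids (samples without
#'   events count in class 0).
#' @param chroms character vector of all chromosome names.
#' @return List with `class_freq` (pooled over chromosomes: `n_events`,
#'   `count`, `freq`), `per_chrom` (frequency matrix classes x
#'   chromosomes), `mean_per_sample`, `se_per_sample`, `total_events`,
#'   `n_samples`.
#' @export
count_per_chromosome <- function(events, samples, chroms) {
  events <- data.table::as.data.table(events)
  ns <- length(samples)
  counts <- matrix(0L, ns, length(chroms),
                   dimnames = list(samples, chroms))
  if (nrow(events)) {
    tab <- events[, .N, by = .(sample, chrom)]
    si <- match(tab$sample, samples)
    ci <- match(tab$chrom, chroms)
    ok <- !is.na(si) & !is.na(ci)
    counts[cbind(si[ok], ci[ok])] <- tab$N[ok]
  }
  kmax <- max(counts)
  classes <- 0:kmax
  pooled <- tabulate(as.vector(counts) + 1L, nbins = kmax + 1L)
  per_chrom <- matrix(vapply(seq_along(chroms), function(j)
    tabulate(counts[, j] + 1L, nbins = kmax + 1L) / ns,
    numeric(kmax + 1L)),
    nrow = kmax + 1L, dimnames = list(classes, chroms))
  per_sample <- rowSums(counts)
  list(
    class_freq = data.table::data.table(n_events = classes, count = pooled,
                                        freq = pooled / sum(pooled)),
    per_chrom = per_chrom,
    mean_per_sample = sum(per_sample) / ns,
    se_per_sample = stats::sd(per_sample) / sqrt(ns),
    total_events = sum(per_sample),
    n_samples = ns
  )
}

#' Chi-square goodness of fit between two event-class distributions
#'
#' Compares event-class count distributions. If `ref` sums to 1 it is
#' taken as a fixed reference distribution and the classic one-sample
#' goodness-of-fit statistic `sum((O - E)^2 / E)` is computed. If `ref`
#' is a second vector of counts, its own sampling noise matters and the
#' standard two-sample chi-square test of homogeneity (2 x k contingency
#' table) is used instead - treating random counts as fixed proportions
#' would anticonservatively inflate the statistic. In both cases classes
#' are pooled from the upper tail until every expected count is at
#' least 1.
#'
#' @param obs_counts integer vector of class counts (classes 0, 1, 2, ...).
#' @param ref reference class proportions (summing to 1) or a second
#'   vector of class counts.
#' @return List with `statistic`, `df`, `p_value`, and the pooled
#'   `observed` / `expected` vectors (expected under the fitted null).
#' @export
chi2_goodness_of_fit <- function(obs_counts, ref) {
  k <- max(length(obs_counts), length(ref))
  o <- c(obs_counts, rep(0, k - length(obs_counts)))
  r <- c(ref, rep(0, k - length(ref)))
  if (sum(o) == 0 || sum(r) == 0) stop("zero total count")
  fixed_ref <- abs(sum(r) - 1) < 1e-8
  # pool upper-tail classes until expected counts under the null are >= 1
  pool_ok <- function(o, r) {
    if (fixed_ref) e <- sum(o) * r / sum(r)
    else e <- sum(o) * (o + r) / (sum(o) + sum(r))
    all(e >= 1) && all((o + r) > 0)
  }
  while (length(o) > 1L && !pool_ok(o, r)) {
    j <- length(o)
    o[j - 1L] <- o[j - 1L] + o[j]
    r[j - 1L] <- r[j - 1L] + r[j]
    o <- o[-j]; r <- r[-j]
  }
  if (fixed_ref) {
    if (any(r == 0)) stop("reference distribution has empty support")
    e <- sum(o) * r / sum(r)
    stat <- sum((o - e)^2 / e)
    df <- length(e) - 1L
  } else {
    n1 <- sum(o); n2 <- sum(r)
    p <- (o + r) / (n1 + n2)
    e <- n1 * p
    e2 <- n2 * p
    stat <- sum((o - e)^2 / e) + sum((r - e2)^2 / e2)
    df <- length(o) - 1L
  }
  p_value <- if (df < 1L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p_value,
       observed = o, expected = e)
}

#' Write events as BED
#'
#' BED intervals `[left - 1, right)` (0-based half-open) with the sample
#' id as name.
#'
#' @param events a [detect_events()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(events, path) {
  bed <- data.table::data.table(chrom = events$chrom,
                                start = as.integer(events$left - 1),
                                end = as.integer(events$right),
                                name = events$sample, score = 1L)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
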