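#' Sliding-window recombination landscape (cM/Mbp)
#'
#' Scans each chromosome in sliding windows, counts the crossover events
#' whose midpoint falls inside each window, and converts counts to genetic
#' distance: `cM = 100 * count / N` (the percentage of gametes recombinant
#' in the window) and `cM/Mbp = cM / span`. Windows are 0-based half-open
#' `[start, start + window)`; the final window is truncated at the
#' chromosome end and its span-adjusted denominator is used.
#'
#' @param events event table with `chrom` and `midpoint` columns
#'   ([detect_events()] or [true_crossovers()]).
#' @param map a [genome_map()] (chromosome lengths).
#' @param n_samples number of gametes in the population (`N`).
#' @param window window width in bp (default 5 Mbp).
#' @param step step between window starts in bp (default 1 Mbp).
#' @return data.table with `chrom`, `start`, `end`, `count`, `cM`,
#'   `cM_per_Mbp`, `n_samples`; class `landscape_track`.
#' @export
recomb_frequency <- function(events, map, n_samples, window = 5e6,
                             step = 1e6) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (!(window >= step && step > 0)) stop("need window >= step > 0")
  events <- data.table::as.data.table(events)
  lens <- chrom_lengths(map)
  out <- list()
  for (cc in names(lens)) {
    L <- lens[[cc]]
    nw <- ceiling(L / step)
    starts <- (seq_len(nw) - 1) * step
    ends <- pmin(starts + window, L)
    cnt <- integer(nw)
    m <- events$midpoint[events$chrom == cc]
    m <- m[m >= 0 & m < L]
    if (length(m)) {
      # window j covers m iff j*step <= m < j*step + window
      j_hi <- pmin(floor(m / step), nw - 1)
      j_lo <- pmax(ceiling((m - window) / step + 1e-9), 0)
      idx <- unlist(lapply(seq_along(m), function(i) j_lo[i]:j_hi[i]))
      tb <- tabulate(idx + 1L, nbins = nw)
      cnt <- tb
    }
    cm <- 100 * cnt / n_samples
    out[[cc]] <- data.table::data.table(
      chrom = cc, start = starts, end = ends, count = cnt, cM = cm,
      cM_per_Mbp = cm / ((ends - starts) / 1e6), n_samples = n_samples)
  }
  tr <- data.table::rbindlist(out)
  data.table::setattr(tr, "class",
                      c("landscape_track", class(tr)))
  tr
}

#' Write a landscape track as BedGraph
#'
#' One line per window with the cM/Mbp value; overlapping windows are
#' written as-is (viewers average them), so for strict BedGraph semantics
#' compute the track with `step = window`.
#'
#' @param track a [recomb_frequency()] result.
#' @param path output path.
#' @param value column to export (default `"cM_per_Mbp"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = "cM_per_Mbp") {
  dt <- data.table::data.table(chrom = track$chrom,
                               start = as.integer(track$start),
                               end = as.integer(track$end),
                               value = track[[value]])
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
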