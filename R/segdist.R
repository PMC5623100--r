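#' Chi-square test against the Mendelian 1:1 ratio
#'
#' One-degree-of-freedom chi-square of observed parental counts against
#' equal expected counts, without continuity correction:
#' `X^2 = (a - b)^2 / (a + b)`.
#'
#' @param a,b non-negative counts (vectorised).
#' @return List with `statistic` and `p_value` (vectors).
#' @export
chi2_1to1 <- function(a, b) {
  if (any(a + b < 1)) stop("zero total count")
  stat <- (a - b)^2 / (a + b)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Allele-frequency track in sliding windows
#'
#' Scans each chromosome in sliding windows (10 Mbp / 1 Mbp step by
#' default) and accumulates parental calls of the binned genotype matrix.
#' The counting unit is either one consensus call per sample per window
#' (`unit = "sample"`, the default: the gamete is the independent
#' replication unit, so the 1:1 test is calibrated) or every bin call
#' pooled (`unit = "bin"`: the windowed average of bin-level allele
#' frequencies; bins of one sample are correlated within a window, which
#' anticonservatively inflates the test and is provided for comparison
#' only). Each window gets a chi-square test against 1:1; windows without
#' calls are flagged (`NA` statistics, no test).
#'
#' @param gm a `geno_matrix` (curated and missing-filtered).
#' @param map a [genome_map()].
#' @param window window width in bp (default 10 Mbp).
#' @param step step between window starts in bp (default 1 Mbp).
#' @param unit `"sample"` or `"bin"` (see above).
#' @return data.table with `chrom`, `start`, `end`, `n1` (parent-1
#'   calls), `n2`, `freq1`, `freq2`, `statistic`, `p_value`; attribute
#'   `chrom_lengths`; class `af_track`.
#' @export
allele_freq_windows <- function(gm, map, window = 10e6, step = 1e6,
                                unit = c("sample", "bin")) {
  unit <- match.arg(unit)
  if (!(window >= step && step > 0)) stop("need window >= step > 0")
  lens <- chrom_lengths(map)
  out <- list()
  for (cc in names(lens)) {
    L <- lens[[cc]]
    rows <- which(gm$bins$chrom == cc)
    nw <- ceiling(L / step)
    starts <- (seq_len(nw) - 1) * step
    ends <- pmin(starts + window, L)
    n1 <- n2 <- numeric(nw)
    if (length(rows)) {
      I1 <- (gm$geno[rows, , drop = FALSE] == 2L)
      I2 <- (gm$geno[rows, , drop = FALSE] == 0L)
      I1[is.na(I1)] <- FALSE
      I2[is.na(I2)] <- FALSE
      bs <- gm$bins$start[rows]
      be <- gm$bins$end[rows]
      cs1 <- rbind(0, apply(I1, 2, cumsum))
      cs2 <- rbind(0, apply(I2, 2, cumsum))
      for (w in seq_len(nw)) {
        hit <- which(bs >= starts[w] & be <= ends[w])
        if (!length(hit)) next
        w1 <- cs1[hit[length(hit)] + 1L, ] - cs1[hit[1L], ]
        w2 <- cs2[hit[length(hit)] + 1L, ] - cs2[hit[1L], ]
        if (unit == "sample") {
          n1[w] <- sum(w1 > w2)
          n2[w] <- sum(w2 > w1)
        } else {
          n1[w] <- sum(w1)
          n2[w] <- sum(w2)
        }
      }
    }
    tot <- n1 + n2
    stat <- p <- rep(NA_real_, nw)
    hasdata <- tot >= 1
    if (any(hasdata)) {
      ct <- chi2_1to1(n1[hasdata], n2[hasdata])
      stat[hasdata] <- ct$statistic
      p[hasdata] <- ct$p_value
    }
    out[[cc]] <- data.table::data.table(
      chrom = cc, start = starts, end = ends, n1 = n1, n2 = n2,
      freq1 = ifelse(tot > 0, n1 / tot, NA_real_),
      freq2 = ifelse(tot > 0, n2 / tot, NA_real_),
      statistic = stat, p_value = p)
  }
  tr <- data.table::rbindlist(out)
  data.table::setattr(tr, "chrom_lengths", lens)
  data.table::setattr(tr, "class", c("af_track", class(tr)))
  tr
}

#' Call segregation distortion regions
#'
#' Flags windows whose 1:1 test is significant at `alpha` (optionally
#' after multiple-testing adjustment) and merges overlapping or adjacent
#' significant windows of the same direction into maximal regions. The
#' genome-wide summary reports the percentage of the genome inside
#' significant windows (union of base pairs, so overlapping windows are
#' never double-counted).
#'
#' @param track an [allele_freq_windows()] result.
#' @param alpha significance level (default 0.05, uncorrected).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (`"none"` default; e.g. `"BH"`, `"bonferroni"`).
#' @return Object of class `sdr_scan`: `regions` (data.table with
#'   `chrom`, `start`, `end`, `size`, `frac_chrom` in %, `direction`
#'   (`"parent1"`/`"parent2"` over-transmitted), `min_p`, `n_windows`),
#'   `genome_pct` (percent of genome in significant windows),
#'   `sig_window_rate` (fraction of testable windows significant),
#'   `alpha`, `adjust`.
#' @export
call_sdrs <- function(track, alpha = 0.05, adjust = "none") {
  lens <- attr(track, "chrom_lengths")
  p_adj <- stats::p.adjust(track$p_value, method = adjust)
  sig <- !is.na(p_adj) & p_adj < alpha
  dir <- ifelse(track$freq1 > 0.5, "parent1", "parent2")
  regions <- list()
  for (cc in unique(track$chrom)) {
    idx <- which(track$chrom == cc & sig)
    if (!length(idx)) next
    idx <- idx[order(track$start[idx])]
    cur <- NULL
    flush <- function(cur) {
      data.table::data.table(
        chrom = cc, start = cur$start, end = cur$end,
        size = cur$end - cur$start,
        frac_chrom = 100 * (cur$end - cur$start) / lens[[cc]],
        direction = cur$dir, min_p = cur$min_p, n_windows = cur$n)
    }
    for (i in idx) {
      if (!is.null(cur) && track$start[i] <= cur$end &&
          dir[i] == cur$dir) {
        cur$end <- max(cur$end, track$end[i])
        cur$min_p <- min(cur$min_p, track$p_value[i])
        cur$n <- cur$n + 1L
      } else {
        if (!is.null(cur)) regions[[length(regions) + 1L]] <- flush(cur)
        cur <- list(start = track$start[i], end = track$end[i],
                    dir = dir[i], min_p = track$p_value[i], n = 1L)
      }
    }
    regions[[length(regions) + 1L]] <- flush(cur)
  }
  regions <- if (length(regions)) data.table::rbindlist(regions)
  else data.table::data.table(chrom = character(0), start = numeric(0),
                              end = numeric(0), size = numeric(0),
                              frac_chrom = numeric(0),
                              direction = character(0), min_p = numeric(0),
                              n_windows = integer(0))
  # union of significant base pairs (direction-agnostic) per chromosome
  union_bp <- 0
  for (cc in unique(track$chrom)) {
    idx <- which(track$chrom == cc & sig)
    if (!length(idx)) next
    o <- order(track$start[idx])
    s <- track$start[idx][o]; e <- track$end[idx][o]
    cs <- s[1L]; ce <- e[1L]
    for (k in seq_along(s)[-1L]) {
      if (s[k] <= ce) ce <- max(ce, e[k])
      else { union_bp <- union_bp + (ce - cs); cs <- s[k]; ce <- e[k] }
    }
    union_bp <- union_bp + (ce - cs)
  }
  testable <- sum(!is.na(track$p_value))
  structure(list(regions = regions,
                 genome_pct = 100 * union_bp / sum(lens),
                 sig_window_rate = if (testable) sum(sig) / testable else NA,
                 n_sig_windows = sum(sig), n_testable_windows = testable,
                 alpha = alpha, adjust = adjust),
            class = "sdr_scan")
}

#' @export
print.sdr_scan <- function(x, ...) {
  cat("sdr_scan:", nrow(x$regions), "regions;",
      sprintf("%.2f%%", x$genome_pct), "of genome distorted",
      "(alpha =", x$alpha, ", adjust =", x$adjust, ")\n")
  invisible(x)
}

#' Write SDRs as BED
#'
#' Name = over-transmitted parent, score = -10 log10(min P) capped at 1000.
#'
#' @param sdr a [call_sdrs()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdr_bed <- function(sdr, path) {
  r <- sdr$regions
  bed <- data.table::data.table(
    chrom = r$chrom, start = as.integer(r$start), end = as.integer(r$end),
    name = r$direction,
    score = pmin(1000L, as.integer(round(-10 * log10(pmax(r$min_p,
                                                          1e-100))))))
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
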