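#' Binned consensus genotype matrix
#'
#' Aggregates sparse per-SNP parental-origin calls into fixed-width bins
#' (1 Mbp by default) and assigns each sample x bin a consensus code:
#' `2` = parent-1 allele ("Morex"-like), `0` = parent-2 allele
#' ("Barke"-like), `NA` = missing. A bin is called for a sample when it
#' holds at least `min_support` non-missing calls and the majority parent
#' accounts for at least `purity` of them; otherwise it is missing.
#' Bins are 0-based half-open: a marker at 1-based position `p` belongs to
#' bin `floor((p - 1) / bin_size)`.
#'
#' @param calls data.table/data.frame with columns `sample`, `chrom`,
#'   `pos`, `call` (1 = parent 1, 2 = parent 2), e.g. from [read_calls()].
#' @param map a [genome_map()] (defines chromosomes and bin grid).
#' @param bin_size bin width in bp (default 1 Mbp).
#' @param min_support minimum number of calls to attempt a consensus.
#' @param purity minimum majority fraction within a bin.
#' @param samples optional sample ids fixing column order (samples without
#'   calls get all-missing columns).
#' @return An object of class `geno_matrix`: `bins` (data.table with
#'   `chrom`, `start`, `end`, `n_markers`), `geno` (integer matrix bins x
#'   samples with values 0/2/NA), `support` (matrix of call counts),
#'   `samples`, `bin_size`.
#' @export
bin_consensus <- function(calls, map, bin_size = 1e6, min_support = 1,
                          purity = 0.8, samples = NULL) {
  if (bin_size <= 0) stop("bin_size must be positive")
  stopifnot(min_support >= 1, purity >= 0.5, purity <= 1)
  calls <- data.table::as.data.table(calls)
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  bins <- .bin_grid(map, bin_size)
  nb <- nrow(bins)
  ns <- length(samples)
  geno <- matrix(NA_integer_, nb, ns, dimnames = list(NULL, samples))
  support <- matrix(0L, nb, ns, dimnames = list(NULL, samples))
  if (nrow(calls)) {
    cc <- calls[, .(n1 = sum(call == 1L), n2 = sum(call == 2L)),
                by = .(sample, chrom, bin = floor((pos - 1) / bin_size))]
    bi <- match(paste(cc$chrom, cc$bin),
                paste(bins$chrom, bins$start / bin_size))
    si <- match(cc$sample, samples)
    ok <- !is.na(bi) & !is.na(si)
    cc <- cc[ok]; bi <- bi[ok]; si <- si[ok]
    n <- cc$n1 + cc$n2
    f <- pmax(cc$n1, cc$n2) / n
    code <- ifelse(n >= min_support & f >= purity & cc$n1 != cc$n2,
                   ifelse(cc$n1 > cc$n2, 2L, 0L), NA_integer_)
    # an exact tie can satisfy purity only when purity == 0.5; keep missing
    geno[cbind(bi, si)] <- code
    support[cbind(bi, si)] <- n
  }
  structure(list(bins = bins, geno = geno, support = support,
                 samples = samples, bin_size = bin_size),
            class = "geno_matrix")
}

.bin_grid <- function(map, bin_size) {
  out <- lapply(seq_len(nrow(map$chromosomes)), function(i) {
    L <- map$chromosomes$length[i]
    cc <- map$chromosomes$chrom[i]
    nb <- ceiling(L / bin_size)
    start <- (seq_len(nb) - 1) * bin_size
    data.table::data.table(chrom = cc, start = start,
                           end = pmin(start + bin_size, L))
  })
  bins <- data.table::rbindlist(out)
  mk <- data.table::as.data.table(map$markers)
  nm <- mk[, .N, by = .(chrom, bin = floor((pos - 1) / bin_size))]
  bins[, n_markers := 0L]
  idx <- match(paste(nm$chrom, nm$bin), paste(bins$chrom,
                                              bins$start / bin_size))
  bins$n_markers[idx] <- nm$N
  bins
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat("geno_matrix:", nrow(x$bins), "bins x", length(x$samples),
      "samples;", sprintf("%.1f%%", 100 * miss), "missing\n")
  invisible(x)
}

#' Remove high-missingness bins
#'
#' Drops bins whose fraction of missing samples strictly exceeds
#' `max_missing` (bins at exactly the threshold are retained). Marker-free
#' bins are missing in every sample and are therefore always removed.
#'
#' @param gm a [bin_consensus()] matrix.
#' @param max_missing maximum tolerated missing fraction (default 0.5).
#' @return Filtered `geno_matrix`; attribute `removed` holds the per-
#'   chromosome count of dropped bins.
#' @export
filter_missing <- function(gm, max_missing = 0.5) {
  miss <- rowMeans(is.na(gm$geno))
  keep <- miss <= max_missing
  removed <- table(gm$bins$chrom[!keep])
  out <- structure(list(bins = gm$bins[keep],
                        geno = gm$geno[keep, , drop = FALSE],
                        support = gm$support[keep, , drop = FALSE],
                        samples = gm$samples, bin_size = gm$bin_size),
                   class = "geno_matrix")
  attr(out, "removed") <- removed
  out
}

#' Write a genotype matrix to TSV
#'
#' Rows are bins (`chrom`, `start`, `end`), columns are samples, cells are
#' 0 / 2 / NA.
#'
#' @param gm a `geno_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geno_tsv <- function(gm, path) {
  out <- data.table::data.table(chrom = gm$bins$chrom,
                                start = gm$bins$start, end = gm$bins$end)
  out <- cbind(out, data.table::as.data.table(gm$geno))
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a genotype matrix from TSV
#'
#' @param path a file written by [write_geno_tsv()].
#' @return A `geno_matrix` (support counts unavailable: zeros).
#' @export
read_geno_tsv <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "chrom"))
  stopifnot(all(c("chrom", "start", "end") %in% names(dt)))
  samples <- setdiff(names(dt), c("chrom", "start", "end"))
  geno <- as.matrix(dt[, samples, with = FALSE])
  storage.mode(geno) <- "integer"
  bins <- dt[, .(chrom, start, end)]
  bins[, n_markers := NA_integer_]
  structure(list(bins = bins, geno = geno,
                 support = matrix(0L, nrow(geno), ncol(geno),
                                  dimnames = list(NULL, samples)),
                 samples = samples,
                 bin_size = if (nrow(bins)) max(bins$end - bins$start) else NA),
            class = "geno_matrix")
}
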