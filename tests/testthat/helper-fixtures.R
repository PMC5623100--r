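# Fixture builders and independent oracles shared across test files.

# small genome for fast tests
tiny_map <- function(n_chrom = 2, length = 60e6, spacing = 1e6,
                     genetic_length = 0.6, map_type = "uniform") {
  chroms <- paste0("tc", seq_len(n_chrom))
  mk <- do.call(rbind, lapply(chroms, function(cc)
    data.frame(chrom = cc, pos = seq(spacing, length, by = spacing),
               parent1 = "A", parent2 = "G")))
  gmap <- lapply(chroms, function(cc) {
    if (map_type == "uniform") uniform_genetic_map(length, genetic_length)
    else distal_genetic_map(length, genetic_length)
  })
  names(gmap) <- chroms
  genome_map(data.frame(chrom = chroms, length = length), mk, gmap)
}

# many short unlinked chromosomes: one 10-Mbp window each, for null
# calibration of the segregation-distortion scan
unlinked_map <- function(n_chrom = 300, length = 10e6, spacing = 2e5,
                         genetic_length = 0.05) {
  chroms <- sprintf("u%04d", seq_len(n_chrom))
  mk <- do.call(rbind, lapply(chroms, function(cc)
    data.frame(chrom = cc, pos = seq(spacing, length, by = spacing),
               parent1 = "A", parent2 = "G")))
  gmap <- stats::setNames(
    lapply(chroms, function(cc) uniform_genetic_map(length, genetic_length)),
    chroms)
  genome_map(data.frame(chrom = chroms, length = length), mk, gmap)
}

# build a geno_matrix directly from a matrix of codes (bins x samples);
# `chrom` gives the chromosome of each row (contiguous blocks)
gm_from_codes <- function(codes, chrom = NULL, bin_size = 1e6) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  nb <- nrow(codes)
  if (is.null(chrom)) chrom <- rep("chrA", nb)
  samples <- colnames(codes)
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(codes)))
  colnames(codes) <- samples
  binof <- stats::ave(seq_len(nb), chrom, FUN = seq_along) - 1
  bins <- data.table::data.table(chrom = chrom, start = binof * bin_size,
                                 end = (binof + 1) * bin_size,
                                 n_markers = 1L)
  structure(list(bins = bins, geno = codes,
                 support = matrix(1L, nb, ncol(codes),
                                  dimnames = list(NULL, samples)),
                 samples = samples, bin_size = bin_size),
            class = "geno_matrix")
}

# matching genome_map for a gm_from_codes fixture (one marker per bin)
map_for_codes <- function(chrom, bin_size = 1e6) {
  tb <- table(factor(chrom, levels = unique(chrom)))
  data.frame(chrom = names(tb), length = as.numeric(tb) * bin_size) -> cl
  mk <- do.call(rbind, lapply(names(tb), function(cc)
    data.frame(chrom = cc,
               pos = (seq_len(tb[[cc]]) - 1) * bin_size + bin_size / 2,
               parent1 = "A", parent2 = "G")))
  genome_map(cl, mk)
}

# brute-force reference for event detection: sign changes of the
# informative subsequence of a single genotype vector
oracle_events <- function(v) {
  idx <- which(!is.na(v))
  if (length(idx) < 2) return(NULL)
  val <- v[idx]
  out <- NULL
  for (j in seq_len(length(idx) - 1)) {
    if (val[j] != val[j + 1])
      out <- rbind(out, data.frame(left_bin = idx[j], right_bin = idx[j + 1],
                                   from = val[j], to = val[j + 1]))
  }
  out
}

# write a VCF from raw text lines (for dialect tests)
write_vcf_text <- function(body, samples, path) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}
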