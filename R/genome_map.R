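#' Genome map for a biparental cross
#'
#' A `genome_map` bundles everything the pipeline needs to know about the
#' cross: chromosome names and physical lengths, the segregating SNP markers
#' with their parental alleles, and (optionally) a genetic map relating
#' physical position to genetic position in Morgans.
#'
#' The genetic map of each chromosome is a monotone piecewise-linear
#' function given as breakpoints `(phys, gen)` with `phys` in bp spanning
#' `[0, L]` and `gen` in Morgans spanning `[0, G]`.
#'
#' @param chromosomes data.frame with columns `chrom` (character) and
#'   `length` (physical length in bp).
#' @param markers data.frame with columns `chrom`, `pos` (1-based bp),
#'   `parent1` and `parent2` (single-nucleotide alleles of the two parents).
#'   Positions must be strictly increasing within a chromosome and lie in
#'   `[1, length]`.
#' @param genetic_map optional named list (one entry per chromosome) of
#'   data.frames with columns `phys` (bp) and `gen` (Morgans), both
#'   non-decreasing, `phys` spanning `[0, L]`.
#'
#' @return An object of class `genome_map`.
#' @export
genome_map <- function(chromosomes, markers, genetic_map = NULL) {
  chromosomes <- as.data.frame(chromosomes)
  markers <- as.data.frame(markers)
  stopifnot(
    all(c("chrom", "length") %in% names(chromosomes)),
    all(c("chrom", "pos", "parent1", "parent2") %in% names(markers)),
    !anyDuplicated(chromosomes$chrom),
    all(chromosomes$length > 0)
  )
  chromosomes$chrom <- as.character(chromosomes$chrom)
  markers$chrom <- as.character(markers$chrom)
  if (!all(markers$chrom %in% chromosomes$chrom))
    stop("markers refer to chromosomes absent from the chromosome table")
  lens <- stats::setNames(chromosomes$length, chromosomes$chrom)
  for (cc in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == cc]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing on ", cc)
    if (any(p < 1) || any(p > lens[[cc]]))
      stop("marker positions outside [1, length] on ", cc)
  }
  if (!is.null(genetic_map)) {
    stopifnot(is.list(genetic_map))
    for (cc in names(genetic_map)) {
      gmc <- genetic_map[[cc]]
      stopifnot(all(c("phys", "gen") %in% names(gmc)))
      if (any(diff(gmc$phys) <= 0) || any(diff(gmc$gen) < 0))
        stop("genetic map must be monotone on ", cc)
      if (utils::tail(gmc$gen, 1) < 0)
        stop("genetic length must be >= 0 on ", cc)
    }
  }
  structure(
    list(chromosomes = chromosomes, markers = markers,
         genetic_map = genetic_map),
    class = "genome_map"
  )
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$markers), "markers\n")
  cat("  total length:",
      formatC(sum(x$chromosomes$length) / 1e6, format = "f", digits = 1),
      "Mbp\n")
  if (!is.null(x$genetic_map))
    cat("  genetic length:",
        formatC(sum(vapply(x$genetic_map, function(g) utils::tail(g$gen, 1),
                           0)) * 100, format = "f", digits = 1), "cM\n")
  invisible(x)
}

#' Chromosome lengths of a genome map
#'
#' @param map a [genome_map()].
#' @return Named numeric vector of physical lengths in bp.
#' @export
chrom_lengths <- function(map) {
  stats::setNames(map$chromosomes$length, map$chromosomes$chrom)
}

#' Genetic length of a chromosome
#'
#' @param map a [genome_map()].
#' @param chrom chromosome name.
#' @return Genetic length in Morgans (0 if the map has no genetic map).
#' @export
genetic_length <- function(map, chrom) {
  if (is.null(map$genetic_map) || is.null(map$genetic_map[[chrom]]))
    return(0)
  utils::tail(map$genetic_map[[chrom]]$gen, 1)
}

#' Uniform genetic map
#'
#' Constant recombination rate along the chromosome: genetic position is
#' proportional to physical position.
#'
#' @param length physical length in bp.
#' @param genetic_length genetic length in Morgans.
#' @return data.frame of `(phys, gen)` breakpoints.
#' @export
uniform_genetic_map <- function(length, genetic_length) {
  data.frame(phys = c(0, length), gen = c(0, genetic_length))
}

#' Distal-elevated genetic map
#'
#' Piecewise-linear map concentrating most of the genetic length in the two
#' distal ends of the chromosome, mimicking the recombination landscape of
#' large-genome cereals where crossovers cluster distally and the
#' (peri-)centromeric interval is recombination-poor. By default the distal
#' 30% of the chromosome (15% per end) carries 90% of the genetic length.
#'
#' @param length physical length in bp.
#' @param genetic_length genetic length in Morgans.
#' @param distal_frac physical fraction of the chromosome per distal end.
#' @param distal_gen_frac genetic fraction per distal end.
#' @return data.frame of `(phys, gen)` breakpoints.
#' @export
distal_genetic_map <- function(length, genetic_length,
                               distal_frac = 0.15, distal_gen_frac = 0.45) {
  stopifnot(distal_frac > 0, distal_frac < 0.5,
            distal_gen_frac > 0, distal_gen_frac <= 0.5)
  data.frame(
    phys = c(0, distal_frac, 1 - distal_frac, 1) * length,
    gen  = c(0, distal_gen_frac, 1 - distal_gen_frac, 1) * genetic_length
  )
}

#' Default synthetic barley-like genome
#'
#' A seven-chromosome genome with physical lengths spanning 558-767 Mbp,
#' one SNP marker per 100 kb, and three 10-Mbp marker-free gaps per
#' chromosome emulating regions of zero polymorphism between the parents.
#' Each chromosome carries a distal-elevated genetic map (see
#' [distal_genetic_map()]) unless `map_type = "uniform"`.
#'
#' @param genetic_length genetic length per chromosome in Morgans.
#' @param marker_spacing distance between consecutive markers in bp.
#' @param map_type `"distal"` (default) or `"uniform"` genetic map shape.
#' @param n_chrom number of chromosomes (at most 7).
#' @return A [genome_map()].
#' @export
default_genome_map <- function(genetic_length = 1.4, marker_spacing = 1e5,
                               map_type = c("distal", "uniform"),
                               n_chrom = 7) {
  map_type <- match.arg(map_type)
  stopifnot(n_chrom >= 1, n_chrom <= 7)
  lens <- c(558, 767, 700, 647, 670, 583, 657)[seq_len(n_chrom)] * 1e6
  chroms <- paste0("chr", seq_len(n_chrom), "H")
  alle <- c("A", "C", "G", "T")
  mk <- lapply(seq_len(n_chrom), function(i) {
    L <- lens[i]
    pos <- seq(marker_spacing, L, by = marker_spacing)
    # three 10-Mbp stretches without segregating SNPs (monomorphic regions)
    gaps <- cbind(start = c(0.35, 0.48, 0.62) * L,
                  end   = c(0.35, 0.48, 0.62) * L + 10e6)
    for (g in seq_len(nrow(gaps)))
      pos <- pos[pos < gaps[g, "start"] | pos >= gaps[g, "end"]]
    k <- seq_along(pos)
    data.frame(chrom = chroms[i], pos = pos,
               parent1 = alle[(k %% 4) + 1],
               parent2 = alle[((k + 1) %% 4) + 1])
  })
  gmap <- lapply(seq_len(n_chrom), function(i) {
    switch(map_type,
           distal  = distal_genetic_map(lens[i], genetic_length),
           uniform = uniform_genetic_map(lens[i], genetic_length))
  })
  names(gmap) <- chroms
  genome_map(data.frame(chrom = chroms, length = lens),
             do.call(rbind, mk), gmap)
}

#' Write the marker table of a genome map to TSV
#'
#' @param map a [genome_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(map, path) {
  data.table::fwrite(map$markers, path, sep = "\t")
  invisible(path)
}

#' Read a marker table from TSV
#'
#' @param path file with columns `chrom`, `pos`, `parent1`, `parent2`.
#' @return data.frame of markers.
#' @export
read_marker_table <- function(path) {
  mk <- data.table::fread(path, colClasses = list(character = "chrom"))
  stopifnot(all(c("chrom", "pos", "parent1", "parent2") %in% names(mk)))
  as.data.frame(mk)
}
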