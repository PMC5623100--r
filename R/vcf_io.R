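#' Write a haploid population VCF
#'
#' Writes one VCF record per marker of the genome map with one haploid GT
#' column per sample: `0` = REF = parent-1 allele, `1` = ALT = parent-2
#' allele, `.` = missing. The file round-trips through [read_calls()].
#'
#' @param pop a [simulate_population()] result, or a data.table of calls
#'   with columns `sample`, `chrom`, `pos`, `call` (1/2).
#' @param map a [genome_map()]; taken from `pop` if omitted.
#' @param path output `.vcf` path (plain text).
#' @param samples sample ids (column order); taken from `pop` if omitted.
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(pop, path, map = NULL, samples = NULL) {
  if (inherits(pop, "gamete_population")) {
    calls <- pop$calls
    if (is.null(map)) map <- pop$map
    if (is.null(samples)) samples <- pop$samples
  } else {
    calls <- data.table::as.data.table(pop)
    if (is.null(map)) stop("map is required when passing a raw call table")
    if (is.null(samples)) samples <- sort(unique(calls$sample))
  }
  mk <- map$markers
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", map$chromosomes$chrom,
            as.integer(map$chromosomes$length)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)),
          collapse = "\t")
  )
  fixed <- paste(mk$chrom, as.integer(mk$pos), ".", mk$parent1, mk$parent2,
                 ".", ".", ".", sep = "\t")
  if (length(samples)) {
    gt <- matrix(".", nrow = nrow(mk), ncol = length(samples))
    if (nrow(calls)) {
      key <- paste(mk$chrom, mk$pos)
      ri <- match(paste(calls$chrom, calls$pos), key)
      ci <- match(calls$sample, samples)
      ok <- !is.na(ri) & !is.na(ci)
      gt[cbind(ri[ok], ci[ok])] <- as.character(calls$call[ok] - 1L)
    }
    body <- paste(fixed, "GT",
                  do.call(paste, c(asplit(gt, 2), sep = "\t")), sep = "\t")
  } else {
    body <- fixed
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read per-SNP parental-origin calls from a VCF
#'
#' Reads haploid genotype calls at known biparental SNP sites and maps
#' each called allele to a parental origin using the marker table. Sites
#' absent from the marker table are dropped (count reported). Haploid GTs
#' (`0`, `1`, `.`) are the native dialect; homozygous diploid GTs
#' (`0/0`, `1|1`, ...) are collapsed to the corresponding haploid call;
#' heterozygous diploid GTs are impossible for a haploid nucleus and are
#' treated as missing (count reported). Called alleles matching neither
#' parent are treated as missing (count reported).
#'
#' @param vcf_path path to a VCF file.
#' @param markers marker table (data.frame with `chrom`, `pos`, `parent1`,
#'   `parent2`) or a [genome_map()].
#' @param verbose log drop counts with [message()].
#' @return data.table with columns `sample`, `chrom`, `pos`, `call`
#'   (1 = parent 1, 2 = parent 2); only non-missing calls are returned.
#'   Attributes `n_dropped_sites`, `n_het_calls`, `n_unmatched_alleles`
#'   carry the QC counts.
#' @export
read_calls <- function(vcf_path, markers, verbose = TRUE) {
  if (inherits(markers, "genome_map")) markers <- markers$markers
  markers <- as.data.frame(markers)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  empty <- data.table::data.table(sample = character(0),
                                  chrom = character(0), pos = numeric(0),
                                  call = integer(0))
  data.table::setattr(empty, "n_dropped_sites", 0L)
  data.table::setattr(empty, "n_het_calls", 0L)
  data.table::setattr(empty, "n_unmatched_alleles", 0L)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty)
  site_key <- paste(fix$CHROM, as.numeric(fix$POS))
  mi <- match(site_key, paste(markers$chrom, as.numeric(markers$pos)))
  n_dropped <- sum(is.na(mi))
  if (verbose && n_dropped)
    message(n_dropped, " VCF sites absent from the marker table; dropped")
  gt <- v@gt
  if (is.null(gt) || ncol(gt) <= 1L) {
    data.table::setattr(empty, "n_dropped_sites", n_dropped)
    return(empty)
  }
  samples <- colnames(gt)[-1L]
  gt <- gt[, -1L, drop = FALSE]
  gt <- sub(":.*", "", gt)                       # strip FORMAT extras
  n_sites <- nrow(fix)
  keepsite <- !is.na(mi)
  # decode GT strings to allele index 0/1/NA; het -> NA (contamination flag)
  u <- unique(as.vector(gt))
  dec <- stats::setNames(rep(NA_integer_, length(u)), u)
  het <- stats::setNames(rep(FALSE, length(u)), u)
  for (s in u) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) next
    a <- strsplit(s, "[/|]")[[1L]]
    a <- a[a != "."]
    if (!length(a) || anyNA(suppressWarnings(as.integer(a)))) next
    ai <- unique(as.integer(a))
    if (length(ai) == 1L) dec[[s]] <- ai else het[[s]] <- TRUE
  }
  gidx <- matrix(dec[as.vector(gt)], n_sites, length(samples))
  n_het <- sum(het[as.vector(gt)], na.rm = TRUE)
  if (verbose && n_het)
    message(n_het, " heterozygous calls in haploid data; treated as missing")
  # called allele sequence -> parental origin, per site
  ref <- fix$REF
  alt <- fix$ALT
  p1 <- markers$parent1[mi]
  p2 <- markers$parent2[mi]
  long <- which(keepsite[row(gidx)] & !is.na(gidx))
  if (!length(long)) {
    data.table::setattr(empty, "n_dropped_sites", n_dropped)
    data.table::setattr(empty, "n_het_calls", n_het)
    return(empty)
  }
  ri <- row(gidx)[long]
  ci <- col(gidx)[long]
  allele <- ifelse(gidx[long] == 0L, ref[ri], alt[ri])
  call <- ifelse(allele == p1[ri], 1L,
                 ifelse(allele == p2[ri], 2L, NA_integer_))
  n_unmatched <- sum(is.na(call))
  if (verbose && n_unmatched)
    message(n_unmatched, " calls match neither parental allele; ",
            "treated as missing")
  ok <- !is.na(call)
  out <- data.table::data.table(sample = samples[ci[ok]],
                                chrom = fix$CHROM[ri[ok]],
                                pos = as.numeric(fix$POS)[ri[ok]],
                                call = call[ok])
  data.table::setorder(out, sample, chrom, pos)
  data.table::setattr(out, "n_dropped_sites", n_dropped)
  data.table::setattr(out, "n_het_calls", n_het)
  data.table::setattr(out, "n_unmatched_alleles", n_unmatched)
  out
}
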