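#' Pipeline run configuration
#'
#' Collects every tunable parameter of the pipeline with its documented
#' default. A configuration either points at real input (`vcf` +
#' `markers` paths) or requests a simulation (`simulate = TRUE`).
#' Configurations round-trip through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    label = "run",
    seed = 1L,
    # input: either a simulation...
    simulate = TRUE,
    n_samples = 40L,
    nu = 3,
    genetic_length = 1.4,
    obligate_co = FALSE,
    map_type = "distal",
    detect_prob = 0.1,
    error_rate = 0.01,
    selection_loci = NULL,       # data.frame(chrom, pos, p1_prob)
    # ...or real files
    vcf = NULL,
    markers = NULL,
    # genotypes
    bin_size = 1e6,
    min_support = 1L,
    purity = 0.8,
    max_missing = 0.5,
    # crossovers
    max_flip_rate = 0.1,
    mask_singletons = FALSE,
    # landscape
    landscape_window = 5e6,
    landscape_step = 1e6,
    # interference
    interference = TRUE,
    nu_grid = seq(0.5, 12, by = 0.25),
    nu_replicates = 400,
    # segregation distortion
    sd_window = 10e6,
    sd_step = 1e6,
    sd_alpha = 0.05,
    sd_adjust = "none",
    sd_unit = "sample"
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  cfg2 <- unclass(cfg)
  if (!is.null(cfg2$selection_loci))
    cfg2$selection_loci <- as.list(as.data.frame(cfg2$selection_loci))
  yaml::write_yaml(cfg2, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$selection_loci))
    raw$selection_loci <- as.data.frame(raw$selection_loci)
  if (!is.null(raw$nu_grid)) raw$nu_grid <- as.numeric(raw$nu_grid)
  do.call(run_config, raw)
}

.validate_config <- function(cfg) {
  if (!isTRUE(cfg$simulate)) {
    if (is.null(cfg$vcf) || is.null(cfg$markers))
      stop("config error: a non-simulation run needs both 'vcf' and ",
           "'markers' paths")
    if (!file.exists(cfg$vcf)) stop("config error: missing VCF: ", cfg$vcf)
    if (!file.exists(cfg$markers))
      stop("config error: missing marker table: ", cfg$markers)
  }
  stopifnot(cfg$bin_size > 0, cfg$purity >= 0.5, cfg$purity <= 1,
            cfg$max_missing >= 0, cfg$max_missing <= 1,
            cfg$sd_alpha >= 0, cfg$sd_alpha <= 1)
  invisible(cfg)
}

#' Run the whole pipeline
#'
#' Orchestrates simulate (or read) -> bin -> filter -> curate -> detect ->
#' landscape -> interference -> segregation-distortion scan, writing every
#' intermediate as TSV/BED plus a YAML manifest of parameters, seed and
#' input checksums. Deterministic given the seed in the configuration.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list of class `pipeline_run` with all in-memory
#'   results (`map`, `matrix`, `events`, `summary`, `landscape`, `fit`,
#'   `track`, `sdr`, `config`, `dir`).
#' @export
run_all <- function(cfg, out_dir) {
  .validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checksums <- list()
  if (isTRUE(cfg$simulate)) {
    map <- default_genome_map(genetic_length = cfg$genetic_length,
                              map_type = cfg$map_type)
    pop <- simulate_population(
      map,
      meiosis_model(nu = cfg$nu, genetic_length = cfg$genetic_length,
                    obligate_co = cfg$obligate_co),
      observation_model(detect_prob = cfg$detect_prob,
                        error_rate = cfg$error_rate),
      selection_model(cfg$selection_loci),
      n = cfg$n_samples, seed = cfg$seed)
    vcf_path <- file.path(out_dir, "population.vcf")
    marker_path <- file.path(out_dir, "markers.tsv")
    write_population_vcf(pop, vcf_path)
    write_marker_table(map, marker_path)
    write_truth(pop, file.path(out_dir, "truth_crossovers.tsv"))
    markers <- map$markers
  } else {
    vcf_path <- cfg$vcf
    marker_path <- cfg$markers
    markers <- read_marker_table(marker_path)
    mk <- data.table::as.data.table(markers)
    lens <- mk[, .(length = max(pos)), by = chrom]
    map <- genome_map(data.frame(chrom = lens$chrom, length = lens$length),
                      markers)
  }
  checksums$vcf <- unname(tools::md5sum(vcf_path))
  checksums$markers <- unname(tools::md5sum(marker_path))

  calls <- read_calls(vcf_path, markers, verbose = FALSE)
  gm <- bin_consensus(calls, map, bin_size = cfg$bin_size,
                      min_support = cfg$min_support, purity = cfg$purity)
  gm <- filter_missing(gm, max_missing = cfg$max_missing)
  cur <- curate(gm, max_flip_rate = cfg$max_flip_rate)
  write_geno_tsv(cur$gm, file.path(out_dir, "genotype_matrix.tsv"))
  data.table::fwrite(cur$report, file.path(out_dir, "curation_report.tsv"),
                     sep = "\t")

  events <- detect_events(cur$gm, mask_singletons = cfg$mask_singletons)
  write_events_bed(events, file.path(out_dir, "events.bed"))
  summary <- count_per_chromosome(events, cur$gm$samples,
                                  map$chromosomes$chrom)
  data.table::fwrite(summary$class_freq,
                     file.path(out_dir, "event_classes.tsv"), sep = "\t")

  track_land <- recomb_frequency(events, map, length(cur$gm$samples),
                                 window = cfg$landscape_window,
                                 step = cfg$landscape_step)
  data.table::fwrite(track_land, file.path(out_dir, "landscape.tsv"),
                     sep = "\t")
  write_bedgraph(track_land, file.path(out_dir, "landscape.bedgraph"))

  fit <- NULL
  if (isTRUE(cfg$interference)) {
    dset <- inter_co_distances(events, map, samples = cur$gm$samples)
    data.table::fwrite(dset$d, file.path(out_dir, "distances.tsv"),
                       sep = "\t")
    fit <- tryCatch(
      estimate_nu(dset, grid = cfg$nu_grid,
                  replicates = cfg$nu_replicates, seed = cfg$seed),
      error = function(e) {
        message("interference fit skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(fit))
      data.table::fwrite(fit$profile,
                         file.path(out_dir, "nu_profile.tsv"), sep = "\t")
  }

  aft <- allele_freq_windows(cur$gm, map, window = cfg$sd_window,
                             step = cfg$sd_step, unit = cfg$sd_unit)
  data.table::fwrite(aft, file.path(out_dir, "allele_freq.tsv"), sep = "\t")
  sdr <- call_sdrs(aft, alpha = cfg$sd_alpha, adjust = cfg$sd_adjust)
  data.table::fwrite(sdr$regions, file.path(out_dir, "sdr_regions.tsv"),
                     sep = "\t")
  write_sdr_bed(sdr, file.path(out_dir, "sdr_regions.bed"))

  manifest <- list(package_version = as.character(utils::packageVersion("sgrec")),
                   config = unclass(write_cfg <- cfg),
                   input_checksums = checksums)
  manifest$config$nu_grid <- as.numeric(manifest$config$nu_grid)
  if (!is.null(manifest$config$selection_loci))
    manifest$config$selection_loci <-
      as.list(as.data.frame(manifest$config$selection_loci))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  res <- structure(list(map = map, matrix = cur$gm,
                        curation = cur$report, events = events,
                        summary = summary, landscape = track_land,
                        fit = fit, track = aft, sdr = sdr, config = cfg,
                        dir = out_dir),
                   class = "pipeline_run")
  invisible(res)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run '", x$config$label, "': ",
      length(x$matrix$samples), " samples, ",
      nrow(x$events), " events, ",
      sprintf("%.1f", x$summary$mean_per_sample), " per gamete; ",
      nrow(x$sdr$regions), " SDRs (", sprintf("%.1f%%", x$sdr$genome_pct),
      " of genome)\n", sep = "")
  invisible(x)
}

#' Compare two pipeline runs (e.g. pollen-like vs DH-like)
#'
#' Joint event-class table with a chi-square goodness-of-fit test of run A
#' against run B's class proportions, side-by-side interference estimates,
#' segregation-distortion genome percentages, and the list of
#' configuration parameters that differ.
#'
#' @param runA,runB results of [run_all()] on the same genome map.
#' @return List of class `population_comparison`.
#' @export
compare_populations <- function(runA, runB) {
  la <- chrom_lengths(runA$map); lb <- chrom_lengths(runB$map)
  if (!identical(la, lb))
    stop("runs use different genome maps; comparison is not meaningful")
  ca <- runA$summary$class_freq$count
  cb <- runB$summary$class_freq$count
  gof <- chi2_goodness_of_fit(ca, cb)
  k <- max(length(ca), length(cb))
  classes <- data.table::data.table(
    n_events = 0:(k - 1),
    countA = c(ca, rep(0L, k - length(ca))),
    countB = c(cb, rep(0L, k - length(cb))))
  diffs <- Filter(
    function(nm) !identical(runA$config[[nm]], runB$config[[nm]]),
    names(runA$config))
  land <- merge(
    runA$landscape[, .(chrom, start, end, cM_per_Mbp_A = cM_per_Mbp)],
    runB$landscape[, .(chrom, start, end, cM_per_Mbp_B = cM_per_Mbp)],
    by = c("chrom", "start", "end"), all = TRUE)
  structure(list(
    event_classes = classes,
    chi2 = gof,
    mean_events = c(A = runA$summary$mean_per_sample,
                    B = runB$summary$mean_per_sample),
    nu = c(A = if (!is.null(runA$fit)) runA$fit$nu else NA,
           B = if (!is.null(runB$fit)) runB$fit$nu else NA),
    sdr_genome_pct = c(A = runA$sdr$genome_pct, B = runB$sdr$genome_pct),
    landscape = land,
    config_diff = diffs,
    labels = c(A = runA$config$label, B = runB$config$label)),
    class = "population_comparison")
}

#' @export
print.population_comparison <- function(x, ...) {
  cat("population_comparison (", x$labels["A"], " vs ", x$labels["B"],
      ")\n", sep = "")
  cat("  mean events/gamete: ", sprintf("%.2f", x$mean_events["A"]), " vs ",
      sprintf("%.2f", x$mean_events["B"]), "\n", sep = "")
  cat("  event-class chi2 P = ", format(x$chi2$p_value, digits = 4), "\n",
      sep = "")
  cat("  SDR genome%: ", sprintf("%.2f", x$sdr_genome_pct["A"]), " vs ",
      sprintf("%.2f", x$sdr_genome_pct["B"]), "\n", sep = "")
  if (length(x$config_diff))
    cat("  differing parameters:", paste(x$config_diff, collapse = ", "),
        "\n")
  invisible(x)
}
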