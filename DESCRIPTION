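Package: sgrec
Title: Recombination Analysis from Single-Gamete Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of meiotic recombination from sparse haploid genotype
    calls of single gametes (e.g. flow-sorted pollen nuclei) or double
    haploid lines of a biparental cross. Per-SNP calls are aggregated into
    megabase-binned consensus genotypes, crossover events are detected as
    parental-origin transitions after curation of error-prone markers,
    recombination landscapes are computed in sliding windows (cM/Mbp),
    crossover interference is estimated by fitting a stationary gamma
    renewal model to inter-crossover distances, and segregation distortion
    regions are delineated by chi-square scans against the Mendelian 1:1
    ratio. A meiosis-and-observation simulator with known ground truth
    (crossover positions, interference strength, transmission bias) makes
    every stage of the pipeline verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
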