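#' @importFrom data.table := .N .SD data.table as.data.table
#' @importFrom stats runif rgamma
NULL

# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", "call", "chrom", "pos", "sample", "bin", "n_markers", "N",
  "d_bp", "L", "n_events", "midpoint", "first", "second", "quadrant",
  "removed", "start", "end", "cM_per_Mbp", "freq"
))
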