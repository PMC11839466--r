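#' @useDynLib fpkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  "V4", "V5", "contig", "start", "end", "group", "count", "pos", "weight",
  "g", "r", "p", "wgt", ".", "chrom", "barcode"
))
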