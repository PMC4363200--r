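#' @useDynLib SporeCall, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom yaml read_yaml write_yaml
NULL
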