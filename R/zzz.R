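#' @importFrom rlang .data
#' @importFrom Rcpp evalCpp
#' @useDynLib mgmtfuse, .registration = TRUE
#' @keywords internal
"_PACKAGE"

.onLoad <- function(libname, pkgname) {
  register_extractor("stub", stub_extract)
  invisible()
}
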