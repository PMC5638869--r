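#' @keywords internal
#' @aliases rifs-package
#' @importFrom Rcpp evalCpp
#' @useDynLib rifs, .registration = TRUE
"_PACKAGE"

.onLoad <- function(libname, pkgname) {
  .register_builtins()
}
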