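#' HostGuestMS: ESI-MS annotation and structural energetics of host-guest
#' inclusion complexes
#'
#' See the package vignette for the underlying models and design choices.
#'
#' @keywords internal
#' @importFrom stats dist rnorm runif setNames
#' @importFrom utils combn write.table
"_PACKAGE"

.onLoad <- function(libname, pkgname) {
  .loadConstants()
}
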