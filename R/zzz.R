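#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.onLoad <- function(libname, pkgname) {
  register_backbone("unet", build_unet)
}
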