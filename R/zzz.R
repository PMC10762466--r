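#' fslmri: full-stack learning of MRI sampling, reconstruction and segmentation
#'
#' A fully differentiable, desk-scale pipeline that jointly learns Cartesian
#' k-space undersampling trajectories, compressed-sensing reconstruction and
#' tissue segmentation on synthetic phantoms.  See `vignette("fslmri-methods")`
#' for the model, its assumptions and the numerical choices.
#'
#' @keywords internal
#' @useDynLib fslmri, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

.onLoad <- function(libname, pkgname) {
  register_default_backbones()
}
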