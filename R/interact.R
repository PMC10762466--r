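# Semantic interaction module (SIM).
#
# Refines the coarse reconstruction conditioned on the coarse segmentation:
# spatially-adaptive normalization blocks at three scales compute per-pixel
# scale and shift from the (differentiable) softmax probability stack, and a
# zero-initialized head makes the module an exact identity at
# initialization (fine = coarse before training).

#' Refine a coarse reconstruction with semantic conditioning
#'
#' @param coarse real H x W matrix.
#' @param coarse_seg H x W x K_total probability array from [segment()].
#' @param params SIM parameters (see [init_fsl_params()]).
#' @return real H x W fine reconstruction.
#' @export
refine <- function(coarse, coarse_seg, params) {
  if (is.null(params)) stop("uninitialized SIM parameters")
  node <- sim_forward(ad_const(array(coarse, c(dim(coarse), 1L))),
                      ad_const(coarse_seg), params)
  node$value[, , 1]
}

#' Squared-L2 fine-reconstruction loss
#'
#' Identical implementation to [loss_coarse()]; an L1 variant is available
#' via `kind = "l1"`.
#' @param fine,target real matrices of the same shape.
#' @param reduction `"mean"` or `"sum"`.
#' @param kind `"l2"` (default) or `"l1"`.
#' @return scalar loss.
#' @export
loss_fine <- function(fine, target, reduction = c("mean", "sum"),
                      kind = c("l2", "l1")) {
  kind <- match.arg(kind)
  if (kind == "l2") return(loss_coarse(fine, target, reduction))
  if (!all(dim(fine) == dim(target))) stop("shape mismatch")
  reduction <- match.arg(reduction)
  d <- abs(fine - target)
  if (reduction == "mean") mean(d) else sum(d)
}
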