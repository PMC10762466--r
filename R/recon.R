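# Spatial-frequency reconstruction module (SFRM).
#
# The default backbone keeps two parallel branches, one on k-space values
# and one on the image, exchanging intermediate representations through
# Fourier projections in each interaction block.  Whatever the backbone,
# the module output passes a final hard data-consistency projection that
# replaces predicted k-space with the measured values at sampled locations.

.backbones <- new.env(parent = emptyenv())

#' Register a reconstruction backbone
#'
#' A backbone is a function `(zf_node, yk_node, mask_matrix, params)` that
#' returns a 2-channel (re, im) image-domain node; the module wrapper adds
#' the data-consistency projection.  Used to swap the dual-domain default
#' for image-domain-only reconstructors.
#'
#' @param name backbone name.
#' @param forward forward function.
#' @param init parameter initializer `(seed)`.
#' @export
register_backbone <- function(name, forward, init) {
  .backbones[[name]] <- list(forward = forward, init = init)
  invisible(name)
}

backbone_get <- function(name) {
  b <- .backbones[[name]]
  if (is.null(b)) stop("unknown reconstruction backbone: ", name)
  b
}

#' List registered reconstruction backbones
#' @return character vector of names.
#' @export
list_backbones <- function() ls(.backbones)

# image-only UNet backbone: zero-filled (re, im) -> residual (re, im)
unet_backbone_forward <- function(zf, yk, maskmat, params) {
  ad_add(zf, unet_forward(zf, params))
}

register_default_backbones <- function() {
  register_backbone("dual", sfrm_forward, function(seed) sfrm_init(seed = seed))
  register_backbone("unet",
                    unet_backbone_forward,
                    function(seed) unet_init(2L, 2L, base = 8L, seed = seed))
}

# graph version: zf/yk are 2-channel nodes, measured_mat a complex matrix.
# Returns list(image = HxWx1 magnitude node, k2 = post-DC 2-channel k node).
sfrm_recon_node <- function(zf, yk, maskmat, measured_mat, params,
                            backbone = "dual", data_consistency = TRUE) {
  bb <- backbone_get(backbone)
  out2 <- bb$forward(zf, yk, maskmat, params)
  kpred <- ad_fft2c(out2)
  if (data_consistency) {
    mask3 <- array(maskmat, c(dim(maskmat), 1L))
    notm <- 1 - mask3[, , c(1L, 1L)]
    dim(notm) <- c(dim(maskmat), 2L)
    meas2 <- two_ch(measured_mat)
    kdc <- ad_addc(ad_mulc(kpred, notm), meas2 * (1 - notm))
    img2 <- ad_fft2c(kdc, inverse = TRUE)
  } else {
    kdc <- kpred
    img2 <- out2
  }
  list(image = ad_cmagnitude(img2), k2 = kdc, image2ch = img2)
}

#' Coarse dual-domain reconstruction
#'
#' @param zero_filled complex H x W matrix (inverse transform of the masked
#'   measurements).
#' @param measured masked `KSpaceData`.
#' @param mask the `SamplingMask` that produced `measured`.
#' @param params SFRM parameters (see [init_fsl_params()]).
#' @param backbone registered backbone name (default `"dual"`).
#' @param data_consistency apply the final hard projection (default TRUE).
#' @param output `"magnitude"` (the module-boundary default) or
#'   `"complex"`.  The data-consistency projection is exact on the
#'   complex-valued image; taking the magnitude discards phase, so the
#'   projection identity should be checked on the complex output.
#' @return real H x W magnitude image, or the complex image.
#' @export
reconstruct_coarse <- function(zero_filled, measured, mask, params,
                               backbone = "dual", data_consistency = TRUE,
                               output = c("magnitude", "complex")) {
  output <- match.arg(output)
  if (is.null(params)) stop("uninitialized SFRM parameters")
  mm <- mask_matrix(mask)
  out <- sfrm_recon_node(ad_const(two_ch(zero_filled)),
                         ad_const(two_ch(measured$values)),
                         mm, measured$values, params,
                         backbone = backbone,
                         data_consistency = data_consistency)
  if (output == "complex") from_two_ch(out$image2ch$value)
  else out$image$value[, , 1]
}

#' Squared-L2 reconstruction loss
#'
#' `mean((coarse - target)^2)` by default; `reduction = "sum"` gives the
#' unreduced squared norm.
#' @param coarse,target real matrices of the same shape.
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return scalar loss.
#' @export
loss_coarse <- function(coarse, target, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!all(dim(coarse) == dim(target))) stop("shape mismatch")
  d <- (coarse - target)^2
  if (reduction == "mean") mean(d) else sum(d)
}
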