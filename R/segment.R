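# Semantic segmentation module (SSM).
#
# A UNet-style encoder-decoder with skip connections segments a magnitude
# image into K anatomical classes (background = 0) plus the appended edge
# class, with a per-pixel softmax head.  The same weights serve the coarse
# and the fine segmentation calls.  The SSM is pretrained on fully sampled
# (clean) images; the progressive trainer then freezes it.

#' Segment an image into class probabilities
#'
#' @param image real H x W matrix (any size; padded internally to a
#'   multiple of 4 and cropped back).
#' @param params SSM parameters (see [init_fsl_params()]).
#' @return H x W x K_total probability array; per-pixel sums are 1.
#' @export
segment <- function(image, params) {
  if (is.null(params)) stop("uninitialized SSM parameters")
  node <- ssm_node(ad_const(array(image, c(dim(image), 1L))), params)
  node$value
}

ssm_node <- function(image_node, params) {
  ad_softmax(unet_forward(image_node, params))
}

#' Pixel-mean cross-entropy segmentation loss
#'
#' `-mean over pixels of log p[true class]`.
#' @param probs H x W x K_total probability array (or node).
#' @param labels integer H x W matrix with classes `0..K_total-1`.
#' @return scalar loss.
#' @export
loss_segmentation <- function(probs, labels) {
  p <- ad_value(probs)
  Kt <- dim(p)[3]
  if (any(labels < 0) || any(labels >= Kt)) stop("label out of range")
  oh <- one_hot(labels, Kt)
  -sum(oh * log(p + 1e-12)) / (dim(p)[1] * dim(p)[2])
}

one_hot <- function(labels, Kt) {
  d <- dim(labels)
  oh <- array(0, c(d, Kt))
  for (k in seq_len(Kt)) oh[, , k] <- labels == (k - 1L)
  oh
}

#' Pretrain the segmentation module on fully sampled images
#'
#' Trains the SSM with cross-entropy on clean images and their auxiliary
#' labels (anatomical + edge classes).  The returned parameters are what
#' stage 1 of the progressive trainer freezes.
#'
#' @param dataset list of `ImageSample`s with `aux_labels` (see
#'   [make_dataset()]).
#' @param config a `TrainConfig` (see [fsl_config()]); uses `lr`, `batch`,
#'   `pretrain_steps`, `seed` and `K`.
#' @param verbose print running loss.
#' @return list with `params` and the per-step `loss` trace.
#' @export
pretrain_ssm <- function(dataset, config, verbose = FALSE) {
  if (length(dataset) == 0) stop("empty dataset")
  Kt <- max(dataset[[1]]$aux_labels) + 1L
  params <- unet_init(1L, Kt, base = 8L, seed = config$seed)
  opt <- adam_init(params, lr = config$lr)
  losses <- numeric(config$pretrain_steps)
  with_seed(config$seed + 1L, {
    for (step in seq_len(config$pretrain_steps)) {
      idx <- sample.int(length(dataset), config$batch, replace = TRUE)
      ad_zero_grad(params)
      tot <- 0
      for (i in idx) {
        s <- dataset[[i]]
        probs <- ssm_node(ad_const(array(s$image, c(dim(s$image), 1L))), params)
        loss <- ad_ce_probs(probs, one_hot(s$aux_labels, Kt))
        ad_backward(loss)
        tot <- tot + loss$value
      }
      losses[step] <- tot / length(idx)
      opt <- adam_step(opt)
      if (verbose && step %% 25 == 0)
        message(sprintf("pretrain step %d loss %.4f", step, losses[step]))
    }
  })
  list(params = params, loss = losses, K_total = Kt)
}
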