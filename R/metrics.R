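# Reconstruction and segmentation metrics plus the evaluation harnesses.
# All metrics are pure functions; repeated calls are bit-identical.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)`; identical inputs give `Inf`.
#' `data_range` defaults to 1, matching images normalized to `[0,1]`.
#' @param pred,target real matrices of the same shape.
#' @param data_range dynamic range (> 0).
#' @return PSNR in dB.
#' @export
psnr <- function(pred, target, data_range = 1) {
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  if (data_range <= 0) stop("data_range must be > 0")
  mse <- mean((pred - target)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index
#'
#' Gaussian-weighted local statistics (sigma 1.5) with the standard
#' stabilisation constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`; the window
#' is 7 for images smaller than 128 pixels and 11 otherwise, evaluated on
#' the interior where the window fits.
#' @param pred,target real matrices of the same shape.
#' @param data_range dynamic range L.
#' @param window odd window size; chosen from the image size when `NULL`.
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(pred, target, data_range = 1, window = NULL) {
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  if (is.null(window)) window <- if (min(dim(pred)) < 128) 7L else 11L
  if (min(dim(pred)) < window) stop("image smaller than the SSIM window")
  k <- gauss_kernel(window, 1.5)
  Th <- valid_filter_mat(nrow(pred), k)
  Tw <- valid_filter_mat(ncol(pred), k)
  f <- function(m) Th %*% m %*% t(Tw)
  mu1 <- f(pred); mu2 <- f(target)
  s11 <- f(pred * pred) - mu1^2
  s22 <- f(target * target) - mu2^2
  s12 <- f(pred * target) - mu1 * mu2
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mean(((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
         ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)))
}

gauss_kernel <- function(w, sigma) {
  x <- seq_len(w) - (w + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# (n - w + 1) x n matrix performing valid 1D correlation with kernel k
valid_filter_mat <- function(n, k) {
  w <- length(k)
  m <- matrix(0, n - w + 1L, n)
  for (i in seq_len(n - w + 1L)) m[i, i + seq_len(w) - 1L] <- k
  m
}

#' Dice similarity coefficient for one class
#'
#' `2|A n B| / (|A| + |B|)`; when the class is absent from both maps the
#' convention is 1.
#' @param pred_labels,target_labels integer matrices of the same shape.
#' @param class_id class to score.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(pred_labels, target_labels, class_id) {
  if (!all(dim(pred_labels) == dim(target_labels))) stop("shape mismatch")
  a <- pred_labels == class_id
  b <- target_labels == class_id
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Macro-averaged foreground Dice
#'
#' Mean DSC over the anatomical tissue classes `1..K-1` (background and the
#' edge class excluded).
#' @param pred_labels,target_labels integer label maps.
#' @param K number of anatomical classes including background.
#' @return mean DSC.
#' @export
dsc_foreground <- function(pred_labels, target_labels, K) {
  mean(vapply(seq_len(K - 1L), function(k)
    dsc(pred_labels, target_labels, k), 0))
}

#' Normalized error map
#'
#' Per-pixel squared (NMSE) or root (NRMSE) error normalized by the target
#' energy, plus the aggregate scalar.  The scalar NRMSE is the square root
#' of the scalar NMSE.
#' @param pred,target real matrices.
#' @param mode `"NMSE"` or `"NRMSE"`.
#' @return list with `map` and scalar `value`.
#' @export
error_map <- function(pred, target, mode = c("NMSE", "NRMSE")) {
  mode <- match.arg(mode)
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  energy <- sum(target^2)
  if (energy == 0) stop("zero-energy target")
  sq <- (pred - target)^2 / energy
  if (mode == "NMSE") list(map = sq, value = sum(sq))
  else list(map = sqrt(sq), value = sqrt(sum(sq)))
}

## ---- evaluation harness ----------------------------------------------------

#' Per-pixel argmax labels from a class-probability stack
#' @param probs H x W x K probability array.
#' @return integer H x W label matrix (classes from 0).
#' @export
seg_labels_from_probs <- function(probs) {
  apply(probs, c(1, 2), which.max) - 1L
}

#' Evaluate a trained model on a test set
#'
#' Runs inference per sample and reports PSNR/SSIM (fine reconstruction vs
#' ground truth), foreground Dice and the zero-filling PSNR of the final
#' trajectory, for every acquisition iteration.
#'
#' @param params trained parameter container.
#' @param test list of `ImageSample`s.
#' @param config a `TrainConfig`.
#' @param ssm_eval result of [pretrain_ssm()]; used to segment paradigms
#'   that carry no semantic modules.
#' @param ablation,fixed_mask forwarded to [fsl_infer()].
#' @param paradigm label written into the report.
#' @param sigma Rician noise level applied to the test images before
#'   k-space synthesis (0 = clean).
#' @return data frame with columns `sample`, `iteration`, `paradigm`,
#'   `sigma`, `psnr`, `ssim`, `dsc`, `psnr_zf`.
#' @export
evaluate_model <- function(params, test, config, ssm_eval = NULL,
                           ablation = list(), fixed_mask = NULL,
                           paradigm = "FSL", sigma = 0) {
  rows <- vector("list", length(test))
  for (j in seq_along(test)) {
    s <- test[[j]]
    img <- s$image
    meas_img <- if (sigma > 0)
      pmin(add_rician_noise(img, sigma, seed = config$seed * 1000L + j), 1)
    else img
    fk <- fft2c(meas_img)
    states <- fsl_infer(fk, config, params, ablation = ablation,
                        fixed_mask = fixed_mask)
    K <- s$meta$K
    per_iter <- lapply(states, function(st) {
      seg_probs <- st$fine_seg %||%
        (if (!is.null(ssm_eval)) segment(st$fine, ssm_eval$params))
      d <- if (!is.null(seg_probs))
        dsc_foreground(seg_labels_from_probs(seg_probs), s$aux_labels, K)
      else NA_real_
      data.frame(sample = j, iteration = st$iteration, paradigm = paradigm,
                 sigma = sigma,
                 psnr = psnr(st$fine, img), ssim = ssim(st$fine, img),
                 dsc = d,
                 psnr_zf = psnr(Mod(st$zero_filled), img))
    })
    rows[[j]] <- do.call(rbind, per_iter)
  }
  do.call(rbind, rows)
}

#' Robustness sweep over Rician noise levels
#'
#' Evaluates the same test samples at each noise level with the same seed;
#' the `sigma = 0` row equals the clean evaluation exactly.
#'
#' @param params trained parameter container.
#' @param test list of `ImageSample`s.
#' @param sigmas noise levels; must include 0.
#' @param config a `TrainConfig`.
#' @param ... forwarded to [evaluate_model()].
#' @return stacked metrics data frame with a `sigma` column.
#' @export
robustness_sweep <- function(params, test, sigmas, config, ...) {
  if (length(sigmas) == 0) stop("empty sigma list")
  if (!any(sigmas == 0)) stop("sigma list must include 0 (clean reference)")
  do.call(rbind, lapply(sigmas, function(sg)
    evaluate_model(params, test, config, sigma = sg, ...)))
}
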