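# Acquisition model: centered orthonormal 2D Fourier transform, binary
# sampling masks with exact budgets, zero-filled reconstruction and the
# hand-crafted baseline trajectories.
#
# Conventions used everywhere in the package:
#  * DC is at the array centre (row floor(H/2)+1, column floor(W/2)+1).
#  * Transforms are orthonormal, so Parseval holds exactly.
#  * A 2D ("pointwise") mask has budget n = round(alpha * H * W); a 1D
#    Cartesian mask acquires whole phase-encoding lines (columns), so its
#    budget is quantized to whole lines: n = H * round(alpha * W), within
#    one line of round(alpha * H * W).

#' Centered orthonormal 2D Fourier transform
#'
#' @param image real or complex H x W matrix.
#' @return a `KSpaceData`: list with complex `values` (DC at centre) and
#'   `centered = TRUE`.
#' @export
forward_fourier <- function(image) {
  stopifnot(all(is.finite(Re(image))), all(is.finite(Im(image))))
  structure(list(values = fft2c(image), centered = TRUE), class = "KSpaceData")
}

#' Inverse centered orthonormal 2D Fourier transform
#' @param kspace a `KSpaceData` or complex matrix.
#' @return complex H x W matrix.
#' @export
inverse_fourier <- function(kspace) {
  v <- if (inherits(kspace, "KSpaceData")) kspace$values else kspace
  ifft2c(v)
}

#' Apply a binary sampling mask to k-space
#'
#' Hadamard product; unsampled entries are exactly zero.
#' @param kspace a `KSpaceData`.
#' @param mask a `SamplingMask`.
#' @return masked `KSpaceData`.
#' @export
apply_mask <- function(kspace, mask) {
  m <- mask_matrix(mask)
  if (!all(dim(kspace$values) == dim(m))) stop("k-space / mask shape mismatch")
  structure(list(values = kspace$values * m, centered = kspace$centered),
            class = "KSpaceData")
}

#' Zero-filled reconstruction
#'
#' Inverse transform of subsampled k-space.  Re-measuring the output at the
#' sampled locations returns the measured values exactly.
#' @param masked masked `KSpaceData`.
#' @return complex image matrix.
#' @export
zero_fill_recon <- function(masked) {
  inverse_fourier(masked)
}

## ---- masks -----------------------------------------------------------------

new_sampling_mask <- function(matrix, kind, rate, seed = NA_integer_,
                              learned = FALSE) {
  storage.mode(matrix) <- "double"
  structure(list(matrix = matrix, kind = kind, rate = rate,
                 budget = as.integer(sum(matrix)), seed = seed,
                 learned = learned),
            class = "SamplingMask")
}

#' @export
print.SamplingMask <- function(x, ...) {
  cat(sprintf("SamplingMask %dx%d kind=%s rate=%.4g budget=%d learned=%s\n",
              nrow(x$matrix), ncol(x$matrix), x$kind, x$rate, x$budget,
              x$learned))
  invisible(x)
}

mask_matrix <- function(mask) {
  if (inherits(mask, "SamplingMask")) mask$matrix else mask
}

#' Budget of a sampling mask
#'
#' `n = round(alpha * H * W)` for pointwise 2D masks (ties rounded half away
#' from zero); for line-structured 1D masks the budget is quantized to whole
#' phase-encoding lines, `H * round(alpha * W)`.
#' @param rate sampling rate in (0, 1].
#' @param H,W grid size.
#' @param kind `"pointwise-2D"` or `"line-1D"`.
#' @return integer number of sampled locations.
#' @export
mask_budget <- function(rate, H, W, kind = c("pointwise-2D", "line-1D")) {
  kind <- match.arg(kind)
  if (kind == "pointwise-2D") round_half_up(rate * H * W)
  else H * round_half_up(rate * W)
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

# DC-centre index along a dimension of size n (matches fftshift convention)
dc_index <- function(n) n %/% 2L + 1L

#' Low-frequency preset mask
#'
#' 2D: the `n` grid points closest to DC in Chebyshev distance (central
#' square, ties broken by Euclidean distance then index); 1D: contiguous
#' central phase-encoding lines.
#'
#' @param rate_fraction fraction of the grid to fill, in (0, 1).
#' @param H,W grid size.
#' @param kind mask kind.
#' @return a `SamplingMask`.
#' @export
center_mask <- function(rate_fraction, H, W, kind = c("pointwise-2D", "line-1D")) {
  kind <- match.arg(kind)
  if (rate_fraction <= 0 || rate_fraction > 1) stop("rate_fraction must be in (0,1]")
  if (kind == "pointwise-2D") {
    n <- round_half_up(rate_fraction * H * W)
    if (n < 1) stop("budget < 1")
    m <- matrix(0, H, W)
    m[center_order(H, W)[seq_len(n)]] <- 1
  } else {
    nl <- round_half_up(rate_fraction * W)
    if (nl < 1) stop("budget < 1 line")
    m <- matrix(0, H, W)
    m[, center_columns(W, nl)] <- 1
  }
  new_sampling_mask(m, kind, rate_fraction)
}

# column-major indices of all grid points ordered by distance from DC
center_order <- function(H, W) {
  cy <- dc_index(H); cx <- dc_index(W)
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  cheb <- pmax(abs(yy - cy), abs(xx - cx))
  eucl <- (yy - cy)^2 + (xx - cx)^2
  order(cheb, eucl, seq_len(H * W))
}

# nl contiguous columns centred on the DC column (clamped to the grid)
center_columns <- function(W, nl) {
  cx <- dc_index(W)
  start <- max(1L, min(cx - nl %/% 2L, W - nl + 1L))
  start + seq_len(nl) - 1L
}

#' Hand-crafted baseline trajectory
#'
#' The fixed, empirically designed masks the learned sampler is compared
#' against.  2D: a central block (about 30% of the budget) plus
#' variable-density random points drawn with Gaussian weights that decay
#' with distance from DC; 1D: central lines plus uniformly random lines.
#' Exact budget, deterministic per seed.
#'
#' @param rate sampling rate alpha in (0, 1).
#' @param H,W grid size.
#' @param kind mask kind.
#' @param seed integer seed.
#' @param center_frac fraction of the budget preset at the centre.
#' @return a `SamplingMask`.
#' @export
fixed_baseline_mask <- function(rate, H, W, kind = c("pointwise-2D", "line-1D"),
                                seed = 1L, center_frac = 0.3) {
  kind <- match.arg(kind)
  if (rate <= 0 || rate >= 1) stop("rate must be in (0,1)")
  with_seed(seed, {
    if (kind == "pointwise-2D") {
      n <- round_half_up(rate * H * W)
      nc <- max(1L, round_half_up(center_frac * n))
      ord <- center_order(H, W)
      m <- matrix(0, H, W)
      cen_idx <- ord[seq_len(nc)]
      m[cen_idx] <- 1
      cy <- dc_index(H); cx <- dc_index(W)
      yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
      r2 <- ((yy - cy) / H)^2 + ((xx - cx) / W)^2
      wgt <- exp(-r2 / (2 * 0.12^2))
      free <- which(m == 0)
      pick <- sample(free, n - nc, prob = wgt[free])
      m[pick] <- 1
    } else {
      nl <- round_half_up(rate * W)
      ncl <- max(1L, round_half_up(center_frac * nl))
      cols <- center_columns(W, ncl)
      free <- setdiff(seq_len(W), cols)
      cols <- c(cols, sample(free, nl - ncl))
      m <- matrix(0, H, W)
      m[, cols] <- 1
    }
    new_sampling_mask(m, kind, rate, seed = seed)
  })
}
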