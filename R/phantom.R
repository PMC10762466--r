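# Synthetic tissue phantoms.
#
# Structured magnitude images that mimic what segmentation-annotated MR
# slices look like statistically: a dark background, one large smooth body
# region and K-2 nested/disjoint blob-shaped tissues with well separated
# mean intensities, modulated by a smooth multiplicative bias field.  Every
# generator is a pure function of its seed.

#' Generate a synthetic tissue phantom
#'
#' Builds a piecewise-smooth magnitude image in `[0,1]` with `K` labelled
#' classes (class 0 = background, class 1 = body, classes `2..K-1` = inner
#' tissue blobs).  Tissue mean intensities are spaced at least 0.15 apart so
#' segmentation ground truth is unambiguous.  Regeneration with the same
#' seed is bit-identical.
#'
#' @param seed integer seed.
#' @param H,W image dimensions (>= 16).
#' @param K number of classes including background (2..8).
#' @return an `ImageSample`: list with `image` (H x W in `[0,1]`),
#'   `label_map` (H x W integers `0..K-1`), `edge_map` (binary H x W) and
#'   `meta`.
#' @export
#' @examples
#' s <- make_phantom(1, 64, 64, 4)
#' table(s$label_map)
make_phantom <- function(seed, H, W, K) {
  if (H < 16 || W < 16) stop("H and W must be >= 16")
  if (K < 2 || K > 8) stop("K must be in 2..8 (distinct intensity levels)")
  with_seed(seed, {
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    cy <- H / 2 + stats::runif(1, -0.05, 0.05) * H
    cx <- W / 2 + stats::runif(1, -0.05, 0.05) * W
    label <- matrix(0L, H, W)

    # body: large deformed ellipse
    body <- blob_mask(yy, xx, cy, cx, ry = 0.38 * H, rx = 0.38 * W,
                      wobble = 0.10, nharm = 3L)
    label[body] <- 1L

    # inner tissues: smaller blobs placed inside the body
    if (K > 2) {
      for (k in 2:(K - 1)) {
        repeat {
          oy <- cy + stats::runif(1, -0.18, 0.18) * H
          ox <- cx + stats::runif(1, -0.18, 0.18) * W
          r <- stats::runif(1, 0.06, 0.13)
          m <- blob_mask(yy, xx, oy, ox, ry = r * H, rx = r * W,
                         wobble = 0.25, nharm = 4L)
          m <- m & body
          if (sum(m) >= 12) break
        }
        label[m] <- as.integer(k)
      }
    }

    # intensities: background near 0, tissue class k at 0.25 + 0.15*(k-1)
    # (consistent across phantoms, like real tissue contrast) with a small
    # per-phantom jitter well below the 0.15 class spacing
    levels <- 0.25 + 0.15 * (seq_len(K - 1) - 1) +
      stats::runif(K - 1, -0.03, 0.03)
    intens <- c(0.02, levels)[label + 1L]
    img <- matrix(intens, H, W)

    # smooth multiplicative bias field (+-8%)
    by <- stats::runif(2, -1, 1)
    bias <- 1 + 0.08 * (by[1] * sin(pi * yy / H + stats::runif(1, 0, pi)) *
                          sin(pi * xx / W + stats::runif(1, 0, pi)) +
                        by[2] * cos(2 * pi * (yy / H - xx / W) / 3))
    img <- pmin(pmax(img * bias, 0), 1)

    edge <- boundary_pixels(label)
    structure(list(
      image = img,
      label_map = label,
      edge_map = edge,
      meta = list(seed = seed, H = H, W = W, K = K)
    ), class = "ImageSample")
  })
}

# deformed ellipse via radial harmonic perturbation
blob_mask <- function(yy, xx, cy, cx, ry, rx, wobble, nharm) {
  dy <- (yy - cy) / ry
  dx <- (xx - cx) / rx
  theta <- atan2(dy, dx)
  r <- sqrt(dy^2 + dx^2)
  pert <- rep(0, length(theta))
  for (h in seq_len(nharm)) {
    pert <- pert + stats::runif(1, -wobble, wobble) / h *
      cos(h * theta + stats::runif(1, 0, 2 * pi))
  }
  r <= 1 + matrix(pert, nrow(yy), ncol(yy))
}

# pixels whose 4-neighbourhood contains a different label and that belong to
# a tissue class (>= 1): the tissue-side inter-class boundary
boundary_pixels <- function(label) {
  H <- nrow(label); W <- ncol(label)
  diff_n <- matrix(FALSE, H, W)
  diff_n[-1, ] <- diff_n[-1, ] | (label[-1, ] != label[-H, ])
  diff_n[-H, ] <- diff_n[-H, ] | (label[-H, ] != label[-1, ])
  diff_n[, -1] <- diff_n[, -1] | (label[, -1] != label[, -W])
  diff_n[, -W] <- diff_n[, -W] | (label[, -W] != label[, -1])
  diff_n & (label >= 1L)
}

# binary dilation with a square structuring element of Chebyshev radius r
dilate_square <- function(m, r) {
  if (r <= 0L) return(m)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  for (di in -r:r) {
    si <- max(1, 1 - di):min(H, H - di)
    ti <- si + di
    for (dj in -r:r) {
      sj <- max(1, 1 - dj):min(W, W - dj)
      tj <- sj + dj
      out[ti, tj] <- out[ti, tj] | m[si, sj]
    }
  }
  out
}

#' Append an edge class to a label map
#'
#' Tissue-boundary pixels (tissue pixels whose 4-neighbourhood contains a
#' different class), dilated to `edge_width`, are relabelled as an extra
#' class `K` appended after the anatomical classes.  Background stays class
#' 0 elsewhere, so foreground/background extraction remains the 0-vs-rest
#' partition.  No pixel farther than `edge_width` (Chebyshev) from a
#' boundary is ever relabelled.
#'
#' @param label_map integer H x W matrix with classes `0..K-1`.
#' @param edge_width edge thickness in pixels (>= 1); width 1 is the raw
#'   boundary, width `w` dilates it by radius `w - 1`.
#' @return integer H x W matrix with classes `0..K` (`K` = edge).
#' @export
derive_aux_labels <- function(label_map, edge_width = 1L) {
  if (edge_width < 1) stop("edge_width must be >= 1")
  K <- max(label_map) + 1L
  edge <- dilate_square(boundary_pixels(label_map), as.integer(edge_width) - 1L)
  out <- label_map
  out[edge] <- K
  out
}

#' Corrupt a magnitude image with Rician noise
#'
#' Adds i.i.d. Gaussian noise of standard deviation `sigma` to the real and
#' imaginary parts (the image itself is the real part) and takes the
#' magnitude, the noise model of magnitude MR images.
#'
#' @param image real matrix.
#' @param sigma noise standard deviation on the `[0,1]` intensity scale.
#' @param seed integer seed.
#' @return real matrix of the same shape.
#' @export
add_rician_noise <- function(image, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(image)
  with_seed(seed, {
    n <- length(image)
    g1 <- matrix(stats::rnorm(n, sd = sigma), nrow(image), ncol(image))
    g2 <- matrix(stats::rnorm(n, sd = sigma), nrow(image), ncol(image))
    sqrt((image + g1)^2 + g2^2)
  })
}

#' Simulate multicoil acquisition from a magnitude image
#'
#' Builds `C` smooth complex coil sensitivity maps (Gaussian magnitude lobes
#' centred on a ring around the image centre, linear phase ramps),
#' normalized so the per-pixel sum of squared magnitudes is exactly 1, and
#' the corresponding per-coil k-space.  With this normalization the
#' root-sum-of-squares of the coil images reproduces the input image.  For
#' `C = 1` the phase ramp is zero, so the single coil is the identity.
#'
#' @param image real H x W matrix.
#' @param C number of coils (>= 1).
#' @param seed integer seed.
#' @return a `CoilSet`: list with `sensitivities` (complex C x H x W, stored
#'   as a list of complex matrices), `per_coil_kspace` (same layout) and
#'   `meta`.
#' @export
simulate_multicoil <- function(image, C, seed = 1L) {
  if (C < 1) stop("C must be >= 1")
  H <- nrow(image); W <- ncol(image)
  with_seed(seed, {
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    sens <- vector("list", C)
    angles <- 2 * pi * (seq_len(C) - 1) / C + stats::runif(1, 0, 2 * pi)
    ring_r <- 0.45 * min(H, W)
    width <- 0.6 * min(H, W)
    for (c in seq_len(C)) {
      cy <- H / 2 + ring_r * sin(angles[c])
      cx <- W / 2 + ring_r * cos(angles[c])
      mag <- exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * width^2))
      if (C == 1L) {
        phase <- matrix(0, H, W)
      } else {
        a <- stats::runif(1, -0.5, 0.5); b <- stats::runif(1, -0.5, 0.5)
        phase <- 2 * pi * (a * yy / H + b * xx / W)
      }
      sens[[c]] <- mag * exp(1i * phase)
    }
    ssq <- Reduce(`+`, lapply(sens, function(s) Mod(s)^2))
    sens <- lapply(sens, function(s) s / sqrt(ssq))
    kspace <- lapply(sens, function(s) fft2c(s * image))
    structure(list(
      sensitivities = sens,
      per_coil_kspace = kspace,
      meta = list(seed = seed, C = C, H = H, W = W)
    ), class = "CoilSet")
  })
}

#' Root-sum-of-squares recombination of a coil set
#' @param coils a `CoilSet`.
#' @return real H x W magnitude image.
#' @export
coil_rss <- function(coils) {
  imgs <- lapply(coils$per_coil_kspace, ifft2c)
  sqrt(Reduce(`+`, lapply(imgs, function(z) Mod(z)^2)))
}

#' Generate a seeded phantom dataset
#'
#' @param n number of samples.
#' @param seed master seed; sample `i` uses `seed * 10000 + i`.
#' @param H,W,K phantom parameters (see [make_phantom()]).
#' @param sigma optional Rician noise level applied to each image.
#' @param edge_width edge-class thickness for the auxiliary labels.
#' @return list of `ImageSample`s, each with an `aux_labels` field
#'   (anatomical classes plus edge class).
#' @export
make_dataset <- function(n, seed = 1L, H = 64L, W = 64L, K = 4L,
                         sigma = 0, edge_width = 1L) {
  lapply(seq_len(n), function(i) {
    s <- make_phantom(seed * 10000 + i, H, W, K)
    if (sigma > 0) {
      s$image <- pmin(add_rician_noise(s$image, sigma, seed * 10000 + i), 1)
    }
    s$aux_labels <- derive_aux_labels(s$label_map, edge_width)
    s
  })
}
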