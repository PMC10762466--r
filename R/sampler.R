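# Measurement sensing module (MSM).
#
# An encoder-decoder predicts, from the previous reconstruction and the
# current trajectory, a per-location probability map over k-space.  The map
# is scaled so its mean matches the per-call target rate, turned into
# Monte-Carlo scores by subtracting a seeded uniform matrix during training,
# and binarized by straight-through top-n selection (2D point sets) or
# top-lines selection (1D Cartesian sets).  Locations already acquired are
# forced to probability zero so they can never be re-sampled.

#' Predict a k-space sampling-probability map
#'
#' @param prev_recon H x W x 2 array (or list of two matrices): magnitude of
#'   the current zero-filled reconstruction and the semantic-prior channel
#'   (the previous fine reconstruction).
#' @param prev_mask `SamplingMask` already acquired; its locations get
#'   probability exactly 0.
#' @param params MSM parameter list from `msm_init()` (see
#'   [init_fsl_params()]).
#' @return a `ProbabilityMap`: list with `probs` (H x W in `[0,1]`) and
#'   `scaled_scores = NULL` (filled by [monte_carlo_scale()]).
#' @export
predict_probability_map <- function(prev_recon, prev_mask, params) {
  if (is.null(params)) stop("uninitialized MSM parameters")
  node <- msm_predict_node(prev_recon_node(prev_recon),
                           mask_matrix(prev_mask), params)
  structure(list(probs = node$value[, , 1], scaled_scores = NULL),
            class = "ProbabilityMap")
}

prev_recon_node <- function(prev_recon) {
  if (is.list(prev_recon) && !is_adnode(prev_recon)) {
    a <- array(0, c(dim(prev_recon[[1]]), 2L))
    a[, , 1] <- prev_recon[[1]]; a[, , 2] <- prev_recon[[2]]
    return(ad_const(a))
  }
  if (is_adnode(prev_recon)) return(prev_recon)
  ad_const(prev_recon)
}

# graph version: prev_recon is an H x W x 2 node; returns H x W x 1 node of
# probabilities with acquired locations zeroed
msm_predict_node <- function(prev_recon, prev_mask_mat, params) {
  mask3 <- array(prev_mask_mat, c(dim(prev_mask_mat), 1L))
  x <- ad_concat(prev_recon, ad_const(mask3))
  probs <- msm_forward(x, params)
  ad_mulc(probs, 1 - mask3)  # re-sampling ban
}

#' Monte-Carlo scale a probability map to a target rate
#'
#' Rescales so the mean equals `target_rate` exactly (multiplicative below
#' the target, complementary above, keeping values in `[0,1]`), then forms
#' stochastic search scores by subtracting a seeded uniform matrix:
#' `scores = rescaled - u`, so the expected fraction of positive scores is
#' the target rate.  With `stochastic = FALSE` (inference) the scores are
#' the rescaled probabilities themselves.
#'
#' @param probs H x W probability matrix (or `ProbabilityMap`).
#' @param target_rate per-call sampling rate in (0, 1).
#' @param seed seed for the uniform matrix.
#' @param stochastic draw the uniform matrix (training) or not (inference).
#' @return a `ProbabilityMap` with `probs` (rescaled) and `scaled_scores`.
#' @export
monte_carlo_scale <- function(probs, target_rate, seed = 1L, stochastic = TRUE) {
  if (target_rate <= 0 || target_rate >= 1) stop("target_rate must be in (0,1)")
  p <- if (inherits(probs, "ProbabilityMap")) probs$probs else probs
  if (all(p == 0)) stop("all-zero probability map cannot be scaled")
  node <- ad_rate_scale(ad_const(array(p, c(dim(p), 1L))), target_rate)
  rescaled <- node$value[, , 1]
  scores <- if (stochastic) {
    u <- with_seed(seed, matrix(stats::runif(length(p)), nrow(p), ncol(p)))
    rescaled - u
  } else rescaled
  structure(list(probs = rescaled, scaled_scores = scores),
            class = "ProbabilityMap")
}

#' Binarize scores to a 2D pointwise mask
#'
#' Exactly the `n` largest scores become 1 (ties broken by row-major index
#' order).  Inside the training graph the same operation runs with a
#' straight-through backward pass.
#'
#' @param scores real matrix (or `ProbabilityMap`).
#' @param n budget.
#' @return a `SamplingMask` of kind `"pointwise-2D"`.
#' @export
binarize_2d <- function(scores, n) {
  s <- score_matrix(scores)
  if (n > length(s)) stop("n exceeds the number of k-space locations")
  m <- topn_select(s, n)
  new_sampling_mask(m, "pointwise-2D", n / length(s), learned = TRUE)
}

#' Binarize scores to a 1D line mask
#'
#' Per-line weights are the sums of scores along the frequency-encoding
#' (row) axis; the top `floor(n_total / H)` lines are set to 1 across the
#' full frequency axis (ties by lowest line index).
#'
#' @param scores real matrix (or `ProbabilityMap`).
#' @param n_total total point budget; quantized down to whole lines.
#' @return a `SamplingMask` of kind `"line-1D"`.
#' @export
binarize_1d <- function(scores, n_total) {
  s <- score_matrix(scores)
  H <- nrow(s)
  nl <- n_total %/% H
  if (nl < 1) stop("budget smaller than one line")
  line_w <- colSums(s)
  sel <- order(-line_w, seq_along(line_w))[seq_len(nl)]
  m <- matrix(0, H, ncol(s))
  m[, sel] <- 1
  new_sampling_mask(m, "line-1D", nl / ncol(s), learned = TRUE)
}

score_matrix <- function(scores) {
  if (inherits(scores, "ProbabilityMap")) {
    if (!is.null(scores$scaled_scores)) scores$scaled_scores else scores$probs
  } else scores
}

# graph version of 1D line binarization with straight-through backward:
# column sums -> top-nl lines -> broadcast back to the full grid
ad_toplines_st <- function(scores, nl) {
  v <- scores$value
  H <- dim(v)[1]; W <- dim(v)[2]
  line_w <- colSums(matrix(v[, , 1], H, W))
  sel <- order(-line_w, seq_along(line_w))[seq_len(nl)]
  out <- array(0, dim(v))
  out[, sel, 1] <- 1
  ad_node(out, list(scores), list(function(g) g))
}

#' Accumulate a new trajectory increment onto the acquired mask
#'
#' Elementwise OR; the increments are disjoint by construction (the
#' re-sampling ban), so budgets add exactly.  Overlap is an internal logic
#' error and is rejected.
#'
#' @param prev,new `SamplingMask`s of the same kind and shape.
#' @return the union `SamplingMask`.
#' @export
accumulate_mask <- function(prev, new) {
  pm <- mask_matrix(prev); nm <- mask_matrix(new)
  if (any(pm * nm > 0)) stop("internal error: overlapping trajectory increments")
  m <- pmin(pm + nm, 1)
  new_sampling_mask(m, if (inherits(prev, "SamplingMask")) prev$kind else "pointwise-2D",
                    sum(m) / length(m), learned = TRUE)
}
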