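# Network definitions for the four learned modules.  All architectures are
# deliberately small so the full pipeline trains in minutes on one CPU:
#  * MSM  - 4-level convolutional encoder-decoder -> k-space probability map
#  * SFRM - two interacting k-space / image-domain branches + hard data
#           consistency (dual-domain contract); a pluggable image-only UNet
#           backbone is registered alongside it
#  * SSM  - UNet-style encoder-decoder with skip connections, softmax head
#  * SIM  - residual refiner whose normalization layers take per-pixel scale
#           and shift from the segmentation stack at three scales

## ---- seeded RNG helper -----------------------------------------------------

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not perturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  # derived seeds (e.g. master*10000 + i) may exceed the 32-bit integer
  # range; wrap them deterministically
  set.seed(as.integer(abs(seed) %% 2147483647))
  force(code)
}

## ---- parameter construction ------------------------------------------------

conv_param <- function(cin, cout, kh = 3L, kw = 3L,
                       init = c("xavier", "uniform", "zero")) {
  init <- match.arg(init)
  fan_in <- kh * kw * cin
  fan_out <- kh * kw * cout
  w <- switch(init,
    xavier = matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / (fan_in + fan_out))),
                    fan_in, cout),
    uniform = matrix(stats::runif(fan_in * cout,
                                  -sqrt(6 / (fan_in + fan_out)),
                                  sqrt(6 / (fan_in + fan_out))), fan_in, cout),
    zero = matrix(0, fan_in, cout)
  )
  list(w = ad_param(w), b = ad_param(rep(0, cout)), kh = kh, kw = kw)
}

conv_apply <- function(x, p) ad_conv(x, p$w, p$b, p$kh, p$kw)

#' Deep-copy parameter values (detached from any optimiser state)
#' @keywords internal
params_clone <- function(params) {
  rapply2(params, function(p) {
    q <- ad_param(p$value)
    q
  })
}

# apply fn to every adnode inside a nested structure, preserving shape
rapply2 <- function(x, fn) {
  if (is_adnode(x)) return(fn(x))
  if (is.list(x)) return(lapply(x, rapply2, fn = fn))
  x
}

#' Checksum of all parameter values (used to verify freezing)
#' @param params nested list of parameter nodes.
#' @return a single numeric digest.
#' @export
params_checksum <- function(params) {
  vals <- unlist(lapply(ad_flatten(params), function(p) as.vector(p$value)))
  sum(vals * seq_along(vals) %% 97)
}

## ---- padding contract ------------------------------------------------------

# zero-pad bottom/right so H and W are multiples of `mult`; crop afterwards
ad_pad_br <- function(a, ph, pw) {
  if (ph == 0L && pw == 0L) return(a)
  v <- a$value
  d <- dim(v)
  out <- array(0, c(d[1] + ph, d[2] + pw, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- v
  ad_node(out, list(a), list(function(g) g[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]))
}

ad_crop_br <- function(a, H, W) {
  v <- a$value
  d <- dim(v)
  if (d[1] == H && d[2] == W) return(a)
  ad_node(v[seq_len(H), seq_len(W), , drop = FALSE], list(a), list(function(g) {
    gi <- array(0, d)
    gi[seq_len(H), seq_len(W), ] <- g
    gi
  }))
}

pad_mult <- function(n, mult) as.integer((mult - n %% mult) %% mult)

## ---- MSM: sampling-probability encoder-decoder -----------------------------

msm_init <- function(in_ch = 3L, seed = 1L) {
  with_seed(seed, list(
    e1 = conv_param(in_ch, 8L, init = "uniform"),
    e2 = conv_param(8L, 16L, init = "uniform"),
    e3 = conv_param(16L, 16L, init = "uniform"),
    e4 = conv_param(16L, 16L, init = "uniform"),
    d3 = conv_param(16L, 16L, init = "uniform"),
    d2 = conv_param(16L, 16L, init = "uniform"),
    d1 = conv_param(16L, 8L, init = "uniform"),
    out = conv_param(8L, 1L, kh = 1L, kw = 1L, init = "uniform")
  ))
}

msm_forward <- function(x, p) {
  h1 <- ad_lrelu(conv_apply(x, p$e1))          # H
  h2 <- ad_lrelu(conv_apply(ad_pool2(h1), p$e2))  # H/2
  h3 <- ad_lrelu(conv_apply(ad_pool2(h2), p$e3))  # H/4
  h4 <- ad_lrelu(conv_apply(ad_pool2(h3), p$e4))  # H/8
  u3 <- ad_lrelu(conv_apply(ad_up2(h4), p$d3))
  u2 <- ad_lrelu(conv_apply(ad_up2(u3), p$d2))
  u1 <- ad_lrelu(conv_apply(ad_up2(u2), p$d1))
  ad_sigmoid(conv_apply(u1, p$out))           # H x W x 1 probabilities
}

## ---- SFRM: dual-domain reconstruction --------------------------------------

sfrm_init <- function(ch = 16L, blocks = 2L, seed = 1L) {
  with_seed(seed, {
    p <- list(
      k_in = conv_param(3L, ch),   # measured k-space (re, im) + mask channel
      i_in = conv_param(2L, ch),   # zero-filled image (re, im)
      blocks = lapply(seq_len(blocks), function(b) list(
        i2k = conv_param(ch, 2L, kh = 1L, kw = 1L),
        k2i = conv_param(ch, 2L, kh = 1L, kw = 1L),
        k_conv = conv_param(ch + 2L, ch),
        i_conv = conv_param(ch + 2L, ch)
      )),
      i_out = conv_param(ch, 2L, kh = 1L, kw = 1L)
    )
    p
  })
}

# returns a 2-channel image-domain node (pre data consistency)
sfrm_forward <- function(zf, yk, maskmat, p) {
  mask3 <- array(maskmat, c(dim(maskmat), 1L))
  k_feat <- ad_lrelu(conv_apply(ad_concat(yk, ad_const(mask3)), p$k_in))
  i_feat <- ad_lrelu(conv_apply(zf, p$i_in))
  for (blk in p$blocks) {
    k_from_i <- ad_fft2c(conv_apply(i_feat, blk$i2k))
    i_from_k <- ad_fft2c(conv_apply(k_feat, blk$k2i), inverse = TRUE)
    k_feat <- ad_lrelu(conv_apply(ad_concat(k_feat, k_from_i), blk$k_conv))
    i_feat <- ad_lrelu(conv_apply(ad_concat(i_feat, i_from_k), blk$i_conv))
  }
  ad_add(zf, conv_apply(i_feat, p$i_out))  # residual from zero filling
}

## ---- generic UNet ----------------------------------------------------------

unet_init <- function(in_ch, out_ch, base = 8L, seed = 1L,
                      init = "xavier", zero_head = FALSE) {
  with_seed(seed, {
    b <- base
    list(
      base = b,
      c1a = conv_param(in_ch, b, init = init), c1b = conv_param(b, b, init = init),
      c2a = conv_param(b, 2L * b, init = init), c2b = conv_param(2L * b, 2L * b, init = init),
      c3a = conv_param(2L * b, 4L * b, init = init), c3b = conv_param(4L * b, 4L * b, init = init),
      d2a = conv_param(6L * b, 2L * b, init = init), d2b = conv_param(2L * b, 2L * b, init = init),
      d1a = conv_param(3L * b, b, init = init), d1b = conv_param(b, b, init = init),
      head = conv_param(b, out_ch, kh = 1L, kw = 1L,
                        init = if (zero_head) "zero" else init)
    )
  })
}

# 3-resolution UNet with skip connections; input padded bottom/right to a
# multiple of 4 and the output cropped back (the padding contract)
unet_forward <- function(x, p) {
  d <- dim(x$value)
  ph <- pad_mult(d[1], 4L); pw <- pad_mult(d[2], 4L)
  x <- ad_pad_br(x, ph, pw)
  e1 <- ad_lrelu(conv_apply(ad_lrelu(conv_apply(x, p$c1a)), p$c1b))
  e2 <- ad_lrelu(conv_apply(ad_lrelu(conv_apply(ad_pool2(e1), p$c2a)), p$c2b))
  e3 <- ad_lrelu(conv_apply(ad_lrelu(conv_apply(ad_pool2(e2), p$c3a)), p$c3b))
  u2 <- ad_lrelu(conv_apply(ad_lrelu(conv_apply(ad_concat(ad_up2(e3), e2), p$d2a)), p$d2b))
  u1 <- ad_lrelu(conv_apply(ad_lrelu(conv_apply(ad_concat(ad_up2(u2), e1), p$d1a)), p$d1b))
  ad_crop_br(conv_apply(u1, p$head), d[1], d[2])
}

## ---- SIM: spatially-adaptive refinement ------------------------------------

sim_init <- function(seg_ch, ch = 8L, seed = 1L) {
  with_seed(seed, list(
    head = conv_param(1L, ch),
    b1 = spade_block_init(ch, seg_ch),
    b2 = spade_block_init(ch, seg_ch),
    b3 = spade_block_init(ch, seg_ch),
    out = conv_param(ch, 1L, kh = 1L, kw = 1L, init = "zero")  # residual identity init
  ))
}

spade_block_init <- function(ch, seg_ch) {
  list(
    gamma = conv_param(seg_ch, ch),
    beta = conv_param(seg_ch, ch),
    conv = conv_param(ch, ch)
  )
}

# normalize the feature, then modulate with per-pixel scale/shift predicted
# from the segmentation stack; residual add keeps identity reachable
spade_block <- function(feat, seg, p) {
  h <- ad_instnorm(feat)
  gamma <- conv_apply(seg, p$gamma)
  beta <- conv_apply(seg, p$beta)
  h <- ad_add(ad_mul(h, ad_addc(gamma, 1)), beta)
  ad_add(feat, ad_lrelu(conv_apply(h, p$conv)))
}

# coarse: H x W x 1 node; seg: H x W x seg_ch probability node
sim_forward <- function(coarse, seg, p) {
  f <- ad_lrelu(conv_apply(coarse, p$head))
  f <- spade_block(f, seg, p$b1)                      # full scale
  f2 <- spade_block(ad_pool2(f), ad_pool2(seg), p$b2) # half scale
  seg4 <- ad_pool2(ad_pool2(seg))
  f3 <- spade_block(ad_pool2(f2), seg4, p$b3)         # quarter scale
  f <- ad_add(f, ad_up2(ad_add(f2, ad_up2(f3))))
  ad_add(coarse, conv_apply(f, p$out))
}
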