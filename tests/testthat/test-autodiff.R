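# Gradient correctness of the reverse-mode engine against central finite
# differences, on tiny tensors.

fd_check <- function(build_loss, param, n_probe = 6, eps = 1e-6, tol = 1e-6) {
  param$grad <- NULL   # gradients accumulate across backward passes
  loss <- build_loss()
  fslmri:::ad_backward(loss)
  ga <- param$grad
  set.seed(99)
  for (t in seq_len(n_probe)) {
    i <- sample(length(param$value), 1)
    param$value[i] <- param$value[i] + eps
    l1 <- build_loss()$value
    param$value[i] <- param$value[i] - 2 * eps
    l2 <- build_loss()$value
    param$value[i] <- param$value[i] + eps
    expect_lt(abs((l1 - l2) / (2 * eps) - ga[i]), tol)
  }
}

test_that("convolution gradients match finite differences", {
  set.seed(1)
  ad_param <- fslmri:::ad_param
  x <- ad_param(array(rnorm(7 * 6 * 3), c(7, 6, 3)))
  p <- fslmri:::with_seed(2, fslmri:::conv_param(3L, 4L))
  tgt <- array(rnorm(7 * 6 * 4), c(7, 6, 4))
  build <- function() fslmri:::ad_mse(fslmri:::ad_conv(x, p$w, p$b), tgt)
  fd_check(build, x)
  fd_check(build, p$w)
  fd_check(build, p$b)
})

test_that("normalization, softmax and pooling gradients match finite differences", {
  set.seed(2)
  ad_param <- fslmri:::ad_param
  x <- ad_param(array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  oh <- fslmri:::one_hot(matrix(sample(0:2, 64, TRUE), 8, 8), 3L)
  build <- function() {
    h <- fslmri:::ad_instnorm(x)
    h <- fslmri:::ad_pool2(h)
    h <- fslmri:::ad_up2(h)
    p <- fslmri:::ad_softmax(h)
    fslmri:::ad_ce_probs(p, oh)
  }
  fd_check(build, x, tol = 1e-5)
})

test_that("Fourier-layer and magnitude gradients match finite differences", {
  set.seed(3)
  x <- fslmri:::ad_param(array(rnorm(8 * 8 * 2), c(8, 8, 2)))
  tgt <- array(rnorm(8 * 8 * 1), c(8, 8, 1))
  build <- function() {
    k <- fslmri:::ad_fft2c(x)
    z <- fslmri:::ad_fft2c(k, inverse = TRUE)
    fslmri:::ad_mse(fslmri:::ad_cmagnitude(z), tgt)
  }
  fd_check(build, x, tol = 1e-5)
})

test_that("rate-scaling gradients match finite differences in both regimes", {
  set.seed(4)
  for (target in c(0.05, 0.9)) {   # down-scaling and complementary branch
    x <- fslmri:::ad_param(array(runif(6 * 6 * 1, 0.2, 0.8), c(6, 6, 1)))
    tgt <- array(runif(36), c(6, 6, 1))
    build <- function() fslmri:::ad_mse(fslmri:::ad_rate_scale(x, target), tgt)
    fd_check(build, x, tol = 1e-5)
  }
})

test_that("rate scaling achieves the exact mean and stays in [0,1]", {
  set.seed(5)
  for (target in c(0.02, 0.1, 0.5, 0.95)) {
    p <- array(runif(64 * 64), c(64, 64, 1))
    out <- fslmri:::ad_rate_scale(fslmri:::ad_const(p), target)$value
    expect_lt(abs(mean(out) - target), 1e-12)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("straight-through top-n passes gradients unchanged", {
  set.seed(6)
  x <- fslmri:::ad_param(array(rnorm(16), c(4, 4, 1)))
  m <- fslmri:::ad_topn_st(x, 5L)
  loss <- fslmri:::ad_sum(fslmri:::ad_mul(m, fslmri:::ad_const(array(2, c(4, 4, 1)))))
  fslmri:::ad_backward(loss)
  expect_equal(sum(m$value), 5)
  expect_equal(x$grad, array(2, c(4, 4, 1)))  # identity backward
})

test_that("Adam reduces a simple quadratic", {
  w <- fslmri:::ad_param(c(5, -3))
  opt <- fslmri:::adam_init(list(w), lr = 0.1)
  for (i in 1:200) {
    fslmri:::ad_zero_grad(list(w))
    loss <- fslmri:::ad_mse(w, c(1, 2))
    fslmri:::ad_backward(loss)
    opt <- fslmri:::adam_step(opt)
  }
  expect_lt(max(abs(w$value - c(1, 2))), 0.05)
})
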