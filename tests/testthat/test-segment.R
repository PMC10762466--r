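# Segmentation module: softmax contract, cross-entropy oracle, pretraining.

test_that("segmentation outputs normalized class probabilities", {
  set.seed(1)
  params <- fslmri:::unet_init(1L, 5L, base = 8L, seed = 2)
  img <- make_phantom(1, 64, 64, 4)$image
  p <- segment(img, params)
  expect_equal(dim(p), c(64, 64, 5))
  expect_true(all(is.finite(p)))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-6)
  expect_error(segment(img, NULL))

  # input-size agnostic within the padding contract
  img2 <- make_phantom(1, 50, 70, 4)$image[1:49, 1:67]
  p2 <- segment(img2, params)
  expect_equal(dim(p2), c(49, 67, 5))
})

test_that("cross-entropy matches hand-computed oracles on toy stacks", {
  # perfect one-hot prediction
  lab <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  probs <- fslmri:::one_hot(lab, 4L)
  expect_lt(loss_segmentation(probs, lab), 1e-10)

  # uniform prediction over 4 classes -> ln 4 per pixel
  u <- array(0.25, c(2, 2, 4))
  expect_equal(loss_segmentation(u, lab), log(4), tolerance = 1e-9)

  # monotone decreasing in the true-class probability (1-pixel case)
  l1 <- matrix(0L, 1, 1)
  f <- function(p) loss_segmentation(array(c(p, 1 - p), c(1, 1, 2)), l1)
  vals <- vapply(c(0.2, 0.4, 0.6, 0.8), f, 0)
  expect_true(all(diff(vals) < 0))

  # hand oracle on a random 2x2 stack
  set.seed(3)
  raw <- array(runif(2 * 2 * 3), c(2, 2, 3))
  probs <- raw / array(apply(raw, c(1, 2), sum), dim(raw))
  lab <- matrix(c(2L, 0L, 1L, 2L), 2, 2)
  hand <- -mean(sapply(1:4, function(i) {
    r <- (i - 1) %% 2 + 1; c <- (i - 1) %/% 2 + 1
    log(probs[r, c, lab[r, c] + 1])
  }))
  expect_equal(loss_segmentation(probs, lab), hand, tolerance = 1e-9)
  expect_error(loss_segmentation(probs, matrix(7L, 2, 2)))
})

test_that("pretraining converges, is seeded, and suffers under artifacts", {
  pre <- fixture_ssm()
  first <- mean(pre$loss[1:10])
  last <- mean(pre$loss[(length(pre$loss) - 9):length(pre$loss)])
  expect_lt(last, 0.5 * first)

  held <- make_dataset(10, seed = 77)
  d_clean <- sapply(held, function(s)
    dsc_foreground(seg_labels_from_probs(segment(s$image, pre$params)),
                   s$aux_labels, 4))
  expect_gt(mean(d_clean), 0.6)

  # 5%-rate zero-filled inputs degrade the pretrained segmentation
  d_zf <- sapply(held, function(s) {
    m <- fixed_baseline_mask(0.05, 64, 64, seed = 1)
    zf <- Mod(zero_fill_recon(apply_mask(forward_fourier(s$image), m)))
    dsc_foreground(seg_labels_from_probs(segment(zf, pre$params)),
                   s$aux_labels, 4)
  })
  expect_gt(mean(d_clean), mean(d_zf))

  # determinism of a short seeded run
  train <- make_dataset(6, seed = 21)
  cfg <- fsl_config(seed = 5, batch = 2, pretrain_steps = 5)
  a <- pretrain_ssm(train, cfg)
  b <- pretrain_ssm(train, cfg)
  expect_identical(a$loss, b$loss)
  expect_error(pretrain_ssm(list(), cfg))
})
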