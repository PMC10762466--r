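# Dual-domain reconstruction: data-consistency contract, loss, and a small
# training run against the zero-filling baseline.

test_that("reconstruction obeys hard data consistency", {
  set.seed(1)
  img <- make_phantom(4, 64, 64, 4)$image
  k <- forward_fourier(img)
  params <- fslmri:::sfrm_init(seed = 2)

  # full mask: output k-space equals the measurements everywhere
  full <- fslmri:::new_sampling_mask(matrix(1, 64, 64), "pointwise-2D", 1)
  kf <- apply_mask(k, full)
  out <- reconstruct_coarse(zero_fill_recon(kf), kf, full, params,
                            output = "complex")
  expect_lt(max(Mod(forward_fourier(out)$values - k$values)), 1e-5)

  # partial mask: measured entries reproduced at sampled locations
  m <- fixed_baseline_mask(0.2, 64, 64, seed = 3)
  km <- apply_mask(k, m)
  outc <- reconstruct_coarse(zero_fill_recon(km), km, m, params,
                             output = "complex")
  back <- forward_fourier(outc)$values * m$matrix
  expect_lt(max(Mod(back - km$values)), 1e-5)

  # the magnitude boundary output agrees with the complex image
  out <- reconstruct_coarse(zero_fill_recon(km), km, m, params)
  expect_equal(out, Mod(outc), tolerance = 1e-6)

  # untrained parameters still give a finite image of the input shape
  expect_true(all(is.finite(out)))
  expect_equal(dim(out), c(64, 64))
  expect_error(reconstruct_coarse(zero_fill_recon(km), km, m, NULL))
})

test_that("the image-only backbone satisfies the same projection", {
  set.seed(2)
  img <- make_phantom(5, 64, 64, 4)$image
  k <- forward_fourier(img)
  m <- fixed_baseline_mask(0.2, 64, 64, seed = 4)
  km <- apply_mask(k, m)
  expect_true("unet" %in% list_backbones())
  params <- fslmri:::unet_init(2L, 2L, base = 8L, seed = 5)
  out <- reconstruct_coarse(zero_fill_recon(km), km, m, params,
                            backbone = "unet", output = "complex")
  back <- forward_fourier(out)$values * m$matrix
  expect_lt(max(Mod(back - km$values)), 1e-5)
  expect_error(reconstruct_coarse(zero_fill_recon(km), km, m, params,
                                  backbone = "nope"))
})

test_that("reconstruction loss matches its closed forms", {
  a <- matrix(2, 2, 2)
  z <- matrix(0, 2, 2)
  expect_equal(loss_coarse(a, a), 0)
  expect_equal(loss_coarse(a, z, reduction = "sum"), 16)  # 4 * 2^2
  expect_equal(loss_coarse(a, z), 4)
  b <- matrix(rnorm(4), 2, 2)
  expect_equal(loss_coarse(a, b), loss_coarse(b, a))
  expect_error(loss_coarse(a, matrix(0, 3, 3)))
})

test_that("a tiny training run halves the loss and beats zero-filling", {
  train <- make_dataset(20, seed = 11)
  held <- make_dataset(5, seed = 77)
  cfg <- fsl_config(seed = 3, lr = 2e-3, batch = 2, stage_steps = c(200, 0, 0))
  params <- init_fsl_params(cfg, K_total = 5L)
  fixed <- fixed_baseline_mask(0.1, 64, 64, seed = 3)
  abl <- list(semantic = FALSE, sim = FALSE, learned_mask = FALSE)
  tr <- fslmri:::train_steps(train, cfg, params, "sfrm", 200, seed = 99,
                             ablation = abl, fixed_mask = fixed)
  first <- mean(tr[1:10])
  last <- mean(tr[191:200])
  expect_lt(last, 0.5 * first)

  ps <- sapply(held, function(s) {
    st <- fsl_infer(fslmri:::fft2c(s$image), cfg, params,
                    ablation = abl, fixed_mask = fixed)
    c(psnr(st[[1]]$coarse, s$image), psnr(Mod(st[[1]]$zero_filled), s$image))
  })
  expect_gte(mean(ps[1, ]), mean(ps[2, ]))
})
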