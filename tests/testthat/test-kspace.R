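# Fourier acquisition model and mask constructors.

test_that("forward transform is unitary with DC at the centre", {
  img <- make_phantom(1, 64, 64, 4)$image
  k <- forward_fourier(img)
  expect_lt(abs(sqrt(sum(Mod(k$values)^2)) - sqrt(sum(img^2))), 1e-10)

  # constant image: single nonzero at DC with magnitude c * sqrt(H*W)
  cimg <- matrix(0.3, 32, 48)
  kc <- forward_fourier(cimg)$values
  dc <- c(32 %/% 2 + 1, 48 %/% 2 + 1)
  expect_lt(abs(Mod(kc[dc[1], dc[2]]) - 0.3 * sqrt(32 * 48)), 1e-10)
  kc[dc[1], dc[2]] <- 0
  expect_lt(max(Mod(kc)), 1e-10)

  # round trip
  expect_lt(max(Mod(inverse_fourier(k) - img)), 1e-10)
})

test_that("mask application is a Hadamard product and idempotent", {
  img <- make_phantom(2, 64, 64, 4)$image
  k <- forward_fourier(img)
  full <- fslmri:::new_sampling_mask(matrix(1, 64, 64), "pointwise-2D", 1)
  expect_equal(apply_mask(k, full)$values, k$values)

  none <- fslmri:::new_sampling_mask(matrix(0, 64, 64), "pointwise-2D", 0)
  expect_true(all(apply_mask(k, none)$values == 0))

  m <- fixed_baseline_mask(0.3, 64, 64, seed = 1)
  km <- apply_mask(k, m)
  expect_lte(sum(km$values != 0), m$budget)
  expect_equal(apply_mask(km, m)$values, km$values)  # idempotence
  expect_error(apply_mask(k, fslmri:::new_sampling_mask(matrix(1, 32, 32),
                                                        "pointwise-2D", 1)))
})

test_that("zero-filling satisfies the data-consistency projection identity", {
  img <- make_phantom(3, 64, 64, 4)$image
  k <- forward_fourier(img)
  m <- fixed_baseline_mask(0.5, 64, 64, seed = 2)
  km <- apply_mask(k, m)
  zf <- zero_fill_recon(km)
  remeasured <- forward_fourier(zf)$values * m$matrix
  expect_lt(max(Mod(remeasured - km$values)), 1e-10)

  full <- fslmri:::new_sampling_mask(matrix(1, 64, 64), "pointwise-2D", 1)
  expect_lt(max(Mod(zero_fill_recon(apply_mask(k, full)) - img)), 1e-10)
  zero <- apply_mask(k, fslmri:::new_sampling_mask(matrix(0, 64, 64),
                                                   "pointwise-2D", 0))
  expect_true(all(zero_fill_recon(zero) == 0))
})

test_that("centre masks have exact budgets and contiguous structure", {
  m <- center_mask(0.999, 16, 16)
  expect_equal(m$budget, round(0.999 * 256))

  for (f in c(0.04, 0.1, 0.33)) {
    m <- center_mask(f, 64, 64)
    expect_equal(m$budget, fslmri:::round_half_up(f * 64 * 64))
  }

  m1 <- center_mask(0.125, 64, 64, kind = "line-1D")
  cols <- which(colSums(m1$matrix) > 0)
  expect_true(all(diff(cols) == 1))                    # contiguous
  expect_true(all(m1$matrix[, cols] == 1))             # whole lines
  expect_equal(m1$budget, 64 * round(0.125 * 64))
  expect_error(center_mask(0, 64, 64))
})

test_that("baseline trajectories have exact budgets and decaying density", {
  for (rate in c(0.05, 0.08, 0.10, 0.15)) {
    m <- fixed_baseline_mask(rate, 64, 64, seed = 5)
    expect_equal(m$budget, fslmri:::round_half_up(rate * 64 * 64))
    m1 <- fixed_baseline_mask(rate, 64, 64, kind = "line-1D", seed = 5)
    expect_true(all(m1$matrix %in% c(0, 1)))
    expect_true(all(apply(m1$matrix, 2, function(col) all(col == col[1]))))
    expect_equal(m1$budget, 64 * round(rate * 64))
  }
  expect_identical(fixed_baseline_mask(0.1, 64, 64, seed = 9),
                   fixed_baseline_mask(0.1, 64, 64, seed = 9))

  # radial sampling density decreases away from DC
  m <- fixed_baseline_mask(0.15, 64, 64, seed = 3)
  cy <- 33; cx <- 33
  yy <- matrix(1:64, 64, 64); xx <- t(yy)
  r <- sqrt((yy - cy)^2 + (xx - cx)^2)
  bins <- cut(as.vector(r), breaks = seq(0, 46, by = 4))
  dens <- tapply(as.vector(m$matrix), bins, mean)
  dens <- dens[!is.na(dens)]
  expect_lt(cor(seq_along(dens), dens, method = "spearman"), 0)
})
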