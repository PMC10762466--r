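# Synthetic phantom generator, auxiliary labels, Rician noise, multicoil.

test_that("phantom generation is seed-deterministic and label-complete", {
  a <- make_phantom(1, 64, 64, 4)
  b <- make_phantom(1, 64, 64, 4)
  expect_identical(a, b)

  c2 <- make_phantom(2, 64, 64, 4)
  expect_gt(sum(a$label_map != c2$label_map), 0)

  for (K in c(2, 4, 8)) {
    s <- make_phantom(7, 64, 64, K)
    expect_setequal(unique(as.vector(s$label_map)), 0:(K - 1))
    expect_true(all(is.finite(s$image)))
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
})

test_that("phantom rejects invalid sizes and class counts", {
  expect_error(make_phantom(1, 8, 64, 4))
  expect_error(make_phantom(1, 64, 64, 1))
  expect_error(make_phantom(1, 64, 64, 9))
})

test_that("tissue mean intensities are separated across classes", {
  for (seed in 1:5) {
    s <- make_phantom(seed, 64, 64, 5)
    mus <- sapply(1:4, function(k) mean(s$image[s$label_map == k]))
    expect_true(all(diff(sort(mus)) > 0.05))
  }
})

test_that("auxiliary edge labels match a brute-force boundary enumeration", {
  # single class: no boundaries, nothing relabelled
  lab <- matrix(0L, 32, 32)
  expect_identical(derive_aux_labels(lab, 1L), lab)

  # one 10x10 square tissue: the tissue-side boundary ring has 36 pixels
  lab <- matrix(0L, 64, 64)
  lab[20:29, 30:39] <- 1L
  aux <- derive_aux_labels(lab, 1L)
  K <- 2L
  expect_equal(sum(aux == K), 36)
  # brute force: tissue pixels with a 4-neighbour of another class
  brute <- 0L
  for (i in 1:64) for (j in 1:64) {
    if (lab[i, j] >= 1L) {
      nb <- c(if (i > 1) lab[i - 1, j], if (i < 64) lab[i + 1, j],
              if (j > 1) lab[i, j - 1], if (j < 64) lab[i, j + 1])
      if (any(nb != lab[i, j])) brute <- brute + 1L
    }
  }
  expect_equal(sum(aux == K), brute)
})

test_that("edge dilation is monotone and bounded by edge_width", {
  s <- make_phantom(3, 64, 64, 4)
  a1 <- derive_aux_labels(s$label_map, 1L)
  a3 <- derive_aux_labels(s$label_map, 3L)
  K <- 4L
  expect_true(all(which(a1 == K) %in% which(a3 == K)))

  # no pixel farther than edge_width (Chebyshev) from a boundary is relabelled
  bound <- which(internal("boundary_pixels")(s$label_map), arr.ind = TRUE)
  relab <- which(a3 == K & s$label_map != K, arr.ind = TRUE)
  for (r in seq_len(nrow(relab))) {
    d <- min(pmax(abs(bound[, 1] - relab[r, 1]), abs(bound[, 2] - relab[r, 2])))
    expect_lte(d, 3)
  }
})

test_that("Rician noise reduces to identity at sigma = 0 and follows the law", {
  img <- make_phantom(1, 32, 32, 3)$image
  expect_identical(add_rician_noise(img, 0, 5), img)
  expect_error(add_rician_noise(img, -1, 5))

  # zero image: magnitude is Rayleigh(sigma); mean = sigma * sqrt(pi/2)
  z <- matrix(0, 1000, 1000)
  r <- add_rician_noise(z, 1, seed = 9)
  expect_lt(abs(mean(r) - sqrt(pi / 2)) / sqrt(pi / 2), 0.01)

  # magnitude^2 / (2 sigma^2) ~ Exp(1)
  r5 <- add_rician_noise(matrix(0, 400, 250), 1, seed = 10)
  ks <- stats::ks.test(as.vector(r5)^2 / 2, "pexp")
  expect_gt(ks$p.value, 0.01)
})

test_that("noise severity grows monotonically with sigma", {
  img <- make_phantom(2, 64, 64, 4)$image
  mad <- sapply(c(0.5, 1.0, 1.5, 2.0), function(sg)
    mean(abs(add_rician_noise(img, sg, seed = 4) - img)))
  expect_true(all(diff(mad) > 0))
})

test_that("multicoil simulation satisfies the RSS round trip", {
  img <- make_phantom(5, 64, 64, 4)$image
  for (C in c(1, 2, 4, 8)) {
    cs <- simulate_multicoil(img, C, seed = 2)
    ssq <- Reduce(`+`, lapply(cs$sensitivities, function(s) Mod(s)^2))
    expect_lt(max(abs(ssq - 1)), 1e-6)
    expect_lt(max(abs(coil_rss(cs) - img)), 1e-5)
  }
  # C = 1 degenerates to the identity
  c1 <- simulate_multicoil(img, 1, seed = 2)
  expect_lt(max(Mod(c1$sensitivities[[1]] - 1)), 1e-12)
  expect_identical(simulate_multicoil(img, 4, seed = 2),
                   simulate_multicoil(img, 4, seed = 2))
  expect_error(simulate_multicoil(img, 0))
})
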