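# Measurement sensing: probability prediction, Monte-Carlo scaling,
# top-n / top-line binarization, trajectory accumulation.

test_that("predicted probability maps are valid and ban re-sampling", {
  set.seed(1)
  params <- fslmri:::msm_init(seed = 4)
  prev <- list(matrix(runif(64 * 64), 64), matrix(runif(64 * 64), 64))
  m0 <- center_mask(0.02, 64, 64)
  pm <- predict_probability_map(prev, m0, params)
  expect_true(all(pm$probs >= 0 & pm$probs <= 1))
  expect_true(all(pm$probs[m0$matrix == 1] == 0))
  expect_error(predict_probability_map(prev, m0, NULL))
})

test_that("probability-map parameters receive gradients", {
  set.seed(2)
  params <- fslmri:::msm_init(seed = 5)
  x <- fslmri:::ad_const(array(runif(64 * 64 * 2), c(64, 64, 2)))
  m0 <- matrix(0, 64, 64)
  node <- fslmri:::msm_predict_node(x, m0, params)
  fslmri:::ad_backward(fslmri:::ad_mean(node))
  gnorm <- sum(vapply(fslmri:::ad_flatten(params),
                      function(p) sum(abs(p$grad %||% 0)), 0))
  expect_gt(gnorm, 0)
})

test_that("Monte-Carlo scaling hits the target rate exactly", {
  # constant map scales to a constant
  pm <- monte_carlo_scale(matrix(0.5, 32, 32), 0.1, seed = 1, stochastic = FALSE)
  expect_equal(pm$probs, matrix(0.1, 32, 32))

  set.seed(3)
  p <- matrix(runif(64 * 64), 64)
  pm <- monte_carlo_scale(p, 0.1, seed = 2)
  expect_lt(abs(mean(pm$probs) - 0.1), 1e-6)
  expect_error(monte_carlo_scale(matrix(0, 8, 8), 0.1))

  # the expected fraction of positive scores equals the target rate
  frac <- vapply(1:100, function(sd)
    mean(monte_carlo_scale(p, 0.1, seed = sd)$scaled_scores > 0), 0)
  expect_lt(abs(mean(frac) - 0.1), 0.01)
})

test_that("2D binarization matches a full-sort oracle", {
  sc <- matrix(c(0.9, 0.5, 0.2, 0.7), 2, 2, byrow = TRUE)
  m <- binarize_2d(sc, 2L)
  expect_equal(m$matrix, matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(binarize_2d(sc, 4L)$matrix, matrix(1, 2, 2))
  expect_error(binarize_2d(sc, 5L))

  # oracle: positions of the n largest values (row-major tie-break)
  oracle <- function(s, n) {
    rm <- as.vector(t(s))
    keep <- order(-rm, seq_along(rm))[seq_len(n)]
    out <- matrix(0, nrow(s), ncol(s))
    for (k in keep) {
      ri <- (k - 1) %/% ncol(s) + 1
      ci <- (k - 1) %% ncol(s) + 1
      out[ri, ci] <- 1
    }
    out
  }
  set.seed(4)
  for (t in 1:1000) {
    s <- matrix(runif(64), 8, 8)
    n <- sample.int(64, 1)
    expect_identical(binarize_2d(s, n)$matrix, oracle(s, n))
  }
  # ties: duplicated scores resolved by row-major order
  s <- matrix(0.5, 4, 4); s[2, 3] <- 0.9
  expect_identical(binarize_2d(s, 3L)$matrix, oracle(s, 3L))
})

test_that("budget matches n = alpha * M * N at the published operating point", {
  set.seed(5)
  s <- matrix(runif(240 * 240), 240)
  m <- binarize_2d(s, fslmri:::round_half_up(0.05 * 240 * 240))
  expect_equal(m$budget, 2880L)
})

test_that("1D binarization selects whole lines by summed weight", {
  sc <- matrix(c(0.1, 0.9, 0.1, 0.8), 2, 2, byrow = TRUE)  # col sums 0.2, 1.7
  m <- binarize_1d(sc, 2L)  # one line of height 2
  expect_equal(m$matrix, matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(binarize_1d(sc, 4L)$matrix, matrix(1, 2, 2))

  set.seed(6)
  s <- matrix(runif(64 * 64), 64)
  m <- binarize_1d(s, 10 * 64)
  expect_true(all(apply(m$matrix, 2, function(col) all(col == col[1]))))
  expect_error(binarize_1d(s, 10L))  # less than one line
})

test_that("mask accumulation adds budgets and is monotone", {
  set.seed(7)
  a <- binarize_2d(matrix(runif(256), 16), 100L)
  rest <- matrix(-1, 16, 16); rest[a$matrix == 1] <- -2
  b <- binarize_2d(rest + matrix(runif(256), 16) * 0.1, 50L)
  # construct disjoint b: force scores so none of a's cells is chosen
  expect_equal(sum(a$matrix * b$matrix), 0)
  u <- accumulate_mask(a, b)
  expect_equal(u$budget, 150L)
  expect_true(all(u$matrix >= a$matrix))
  expect_identical(accumulate_mask(fslmri:::new_sampling_mask(matrix(0, 16, 16),
                                                              "pointwise-2D", 0),
                                   a)$matrix, a$matrix)
  expect_error(accumulate_mask(a, a))
})

test_that("a loss on the binarized mask back-propagates to the sampler", {
  set.seed(8)
  params <- fslmri:::msm_init(seed = 9)
  x <- fslmri:::ad_const(array(runif(64 * 64 * 2), c(64, 64, 2)))
  probs <- fslmri:::msm_predict_node(x, matrix(0, 64, 64), params)
  scaled <- fslmri:::ad_rate_scale(probs, 0.1)
  mask <- fslmri:::ad_topn_st(scaled, 410L)
  tgt <- array(runif(64 * 64), c(64, 64, 1))
  loss <- fslmri:::ad_mse(mask, tgt)
  fslmri:::ad_backward(loss)
  gnorm <- sum(vapply(fslmri:::ad_flatten(params),
                      function(p) sum(abs(p$grad %||% 0)), 0))
  expect_gt(gnorm, 0)  # straight-through contract
})
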