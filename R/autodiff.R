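# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Every differentiable quantity in the pipeline (network activations, masks,
# losses) is an `adnode`: an environment holding a value, a list of parent
# nodes and, for each parent, a closure mapping the upstream gradient to the
# gradient contribution for that parent.  `ad_backward()` runs a topological
# sweep and accumulates gradients into every node created with
# `ad_param()`.  Activations are H x W x C arrays (channels last); complex
# images travel as two real channels.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

ad_next_id <- function() {
  .ad$id <- .ad$id + 1L
  .ad$id
}

#' Create an autodiff node
#'
#' `ad_const()` wraps a plain array as a leaf that does not require
#' gradients; `ad_param()` wraps a learnable parameter leaf.  Internal nodes
#' are created by the `ad_*` operators.
#'
#' @param value numeric array (any shape).
#' @return an object of class `adnode`.
#' @keywords internal
ad_const <- function(value) ad_node(value, req = FALSE)

#' @rdname ad_const
#' @keywords internal
ad_param <- function(value) ad_node(value, req = TRUE)

ad_node <- function(value, parents = list(), gfns = list(), req = NULL) {
  stopifnot(is.numeric(value))
  if (is.null(req)) req <- any(vapply(parents, function(p) p$req, logical(1)))
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$gfns <- gfns
  e$req <- req
  e$id <- ad_next_id()
  class(e) <- "adnode"
  e
}

is_adnode <- function(x) inherits(x, "adnode")

#' Extract the value of an autodiff node
#' @param x an `adnode` or plain array (returned unchanged).
#' @return the underlying numeric array.
#' @keywords internal
ad_value <- function(x) if (is_adnode(x)) x$value else x

as_adnode <- function(x) if (is_adnode(x)) x else ad_const(x)

#' Run a backward pass from a scalar node
#'
#' Accumulates `$grad` on every ancestor that requires gradients.  The root
#' must be scalar (length-1 value); its seed gradient is 1.
#'
#' @param root scalar `adnode`.
#' @keywords internal
ad_backward <- function(root) {
  stopifnot(is_adnode(root), length(root$value) == 1L)
  # iterative topological order (post-order DFS over requiring nodes)
  order <- vector("list", 256L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (p$req && is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    }
  }
  root$grad <- 1
  if (n_ord >= 1L) {
    for (i in seq(n_ord, 1L)) {
      node <- order[[i]]
      g <- node$grad
      if (is.null(g)) next
      ps <- node$parents
      for (j in seq_along(ps)) {
        p <- ps[[j]]
        if (!p$req) next
        contrib <- node$gfns[[j]](g)
        p$grad <- if (is.null(p$grad)) contrib else p$grad + contrib
      }
    }
  }
  invisible(root)
}

#' Reset gradients on a list of parameter nodes
#' @param params (possibly nested) list of `adnode`s.
#' @keywords internal
ad_zero_grad <- function(params) {
  for (p in ad_flatten(params)) p$grad <- NULL
  invisible(NULL)
}

# flatten a nested list of adnodes into a flat list
ad_flatten <- function(x) {
  if (is_adnode(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, ad_flatten)))
  list()
}

## ---- elementwise arithmetic ------------------------------------------------

ad_add <- function(a, b) {
  a <- as_adnode(a); b <- as_adnode(b)
  ad_node(a$value + b$value, list(a, b), list(function(g) g, function(g) g))
}

ad_sub <- function(a, b) {
  a <- as_adnode(a); b <- as_adnode(b)
  ad_node(a$value - b$value, list(a, b), list(function(g) g, function(g) -g))
}

ad_mul <- function(a, b) {
  a <- as_adnode(a); b <- as_adnode(b)
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b),
          list(function(g) g * bv, function(g) g * av))
}

# multiply by a plain constant array/scalar (no graph edge for the constant)
ad_mulc <- function(a, k) {
  ad_node(a$value * k, list(a), list(function(g) g * k))
}

ad_addc <- function(a, k) {
  ad_node(a$value + k, list(a), list(function(g) g))
}

ad_neg <- function(a) ad_mulc(a, -1)

## ---- activations -----------------------------------------------------------

ad_relu <- function(a) {
  m <- a$value > 0
  ad_node(a$value * m, list(a), list(function(g) g * m))
}

ad_lrelu <- function(a, slope = 0.1) {
  v <- a$value
  m <- ifelse(v > 0, 1, slope)
  ad_node(v * m, list(a), list(function(g) g * m))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(s, list(a), list(function(g) g * s * (1 - s)))
}

ad_tanh <- function(a) {
  t <- tanh(a$value)
  ad_node(t, list(a), list(function(g) g * (1 - t * t)))
}

## ---- shape utilities -------------------------------------------------------

# concatenate along the channel (3rd) dimension
ad_concat <- function(a, b) {
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  stopifnot(length(da) == 3L, all(da[1:2] == db[1:2]))
  ca <- da[3]
  out <- array(0, c(da[1], da[2], ca + db[3]))
  out[, , seq_len(ca)] <- av
  out[, , ca + seq_len(db[3])] <- bv
  ad_node(out, list(a, b), list(
    function(g) g[, , seq_len(ca), drop = FALSE],
    function(g) g[, , ca + seq_len(db[3]), drop = FALSE]
  ))
}

# 2x2 average pooling (H and W must be even)
ad_pool2 <- function(a) {
  v <- a$value
  d <- dim(v)
  H <- d[1]; W <- d[2]; C <- d[3]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  out <- (v[io, jo, , drop = FALSE] + v[io + 1L, jo, , drop = FALSE] +
          v[io, jo + 1L, , drop = FALSE] + v[io + 1L, jo + 1L, , drop = FALSE]) / 4
  ad_node(out, list(a), list(function(g) {
    gi <- array(0, d)
    gq <- g / 4
    gi[io, jo, ] <- gq; gi[io + 1L, jo, ] <- gq
    gi[io, jo + 1L, ] <- gq; gi[io + 1L, jo + 1L, ] <- gq
    gi
  }))
}

# nearest-neighbour 2x upsampling
ad_up2 <- function(a) {
  v <- a$value
  d <- dim(v)
  ii <- rep(seq_len(d[1]), each = 2L)
  jj <- rep(seq_len(d[2]), each = 2L)
  out <- v[ii, jj, , drop = FALSE]
  ad_node(out, list(a), list(function(g) {
    io <- seq(1L, 2L * d[1], 2L); jo <- seq(1L, 2L * d[2], 2L)
    g[io, jo, , drop = FALSE] + g[io + 1L, jo, , drop = FALSE] +
      g[io, jo + 1L, , drop = FALSE] + g[io + 1L, jo + 1L, , drop = FALSE]
  }))
}

## ---- convolution (im2col + GEMM) -------------------------------------------

# unfold an H x W x C array into an (H*W) x (kh*kw*C) matrix, zero padding
im2col <- function(x, kh, kw) {
  d <- dim(x)
  cpp_im2col(x, d[1], d[2], d[3], kh, kw)
}

#' Same-padding 2D convolution
#'
#' `w` is a `(kh*kw*Cin) x Cout` weight node, `b` a length-`Cout` bias node.
#' Stride 1, zero padding to keep the spatial size.  Forward and backward
#' run as fused im2col + GEMM kernels in C; the three gradients (input,
#' weight, bias) are computed in one call and cached for the per-parent
#' closures.
#' @keywords internal
ad_conv <- function(x, w, b, kh = 3L, kw = 3L) {
  xv <- x$value
  d <- dim(xv)
  H <- d[1]; W <- d[2]
  wv <- w$value
  out <- cpp_conv_forward(xv, wv, b$value, H, W, kh, kw)
  cache <- new.env(parent = emptyenv())
  grads <- function(g) {
    if (is.null(cache$g)) cache$g <- cpp_conv_backward(xv, g, wv, H, W, kh, kw)
    cache$g
  }
  ad_node(out, list(x, w, b), list(
    function(g) grads(g)$gx,
    function(g) grads(g)$gw,
    function(g) grads(g)$gb
  ))
}

## ---- normalization ---------------------------------------------------------

# parameter-free per-channel instance normalization over H, W
ad_instnorm <- function(x, eps = 1e-5) {
  v <- x$value
  d <- dim(v)
  N <- d[1] * d[2]
  vm <- v; dim(vm) <- c(N, d[3])
  mu <- colMeans(vm)
  xc <- vm - rep(mu, each = N)
  sd <- sqrt(colMeans(xc * xc) + eps)
  xhat <- xc / rep(sd, each = N)
  out <- xhat; dim(out) <- d
  ad_node(out, list(x), list(function(g) {
    dim(g) <- c(N, d[3])
    gm <- colMeans(g)
    gx <- colMeans(g * xhat)
    gi <- (g - rep(gm, each = N) - xhat * rep(gx, each = N)) / rep(sd, each = N)
    dim(gi) <- d
    gi
  }))
}

## ---- reductions and losses -------------------------------------------------

ad_mean <- function(a) {
  n <- length(a$value)
  ad_node(mean(a$value), list(a), list(function(g) array(g / n, dim(a$value))))
}

ad_sum <- function(a) {
  ad_node(sum(a$value), list(a), list(function(g) array(g, dim(a$value))))
}

# mean (or sum) squared difference against a constant target
ad_mse <- function(a, target, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  diff <- a$value - target
  n <- if (reduction == "mean") length(diff) else 1
  ad_node(sum(diff * diff) / n, list(a),
          list(function(g) g * 2 * diff / n))
}

ad_l1 <- function(a, target) {
  diff <- a$value - target
  n <- length(diff)
  ad_node(sum(abs(diff)) / n, list(a),
          list(function(g) g * sign(diff) / n))
}

# per-pixel channel softmax (class probabilities along dim 3)
ad_softmax <- function(a) {
  v <- a$value
  d <- dim(v)
  N <- d[1] * d[2]; K <- d[3]
  vm <- v; dim(vm) <- c(N, K)
  mx <- vm[, 1]
  if (K > 1) for (k in 2:K) mx <- pmax(mx, vm[, k])
  ex <- exp(vm - mx)
  p <- ex / rowSums(ex)
  out <- p; dim(out) <- d
  ad_node(out, list(a), list(function(g) {
    dim(g) <- c(N, K)
    gp <- g * p
    gi <- gp - p * rowSums(gp)
    dim(gi) <- d
    gi
  }))
}

# pixel-mean cross-entropy of a probability stack against a one-hot stack
ad_ce_probs <- function(p, onehot, eps = 1e-12) {
  v <- p$value
  npix <- dim(v)[1] * dim(v)[2]
  val <- -sum(onehot * log(v + eps)) / npix
  ad_node(val, list(p), list(function(g) g * (-onehot / (v + eps) / npix)))
}

## ---- Fourier layers --------------------------------------------------------

fftshift2 <- function(m) {
  d <- dim(m)
  s1 <- d[1] %/% 2L; s2 <- d[2] %/% 2L
  m[c((s1 + 1L):d[1], seq_len(s1)), c((s2 + 1L):d[2], seq_len(s2)), drop = FALSE]
}

ifftshift2 <- function(m) {
  d <- dim(m)
  s1 <- (d[1] + 1L) %/% 2L; s2 <- (d[2] + 1L) %/% 2L
  m[c((s1 + 1L):d[1], seq_len(s1)), c((s2 + 1L):d[2], seq_len(s2)), drop = FALSE]
}

# centered orthonormal 2D FFT on a complex matrix
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

ifft2c <- function(k) {
  fftshift2(stats::fft(ifftshift2(k), inverse = TRUE)) / sqrt(length(k))
}

two_ch <- function(z) {
  d <- dim(z)
  out <- array(0, c(d[1], d[2], 2L))
  out[, , 1] <- Re(z); out[, , 2] <- Im(z)
  out
}

from_two_ch <- function(a) {
  matrix(complex(real = a[, , 1], imaginary = a[, , 2]), dim(a)[1], dim(a)[2])
}

# centered orthonormal FFT on a 2-channel (re, im) node; the map is unitary,
# so the backward pass is the inverse transform
ad_fft2c <- function(a, inverse = FALSE) {
  fwd <- if (inverse) ifft2c else fft2c
  bwd <- if (inverse) fft2c else ifft2c
  out <- two_ch(fwd(from_two_ch(a$value)))
  ad_node(out, list(a), list(function(g) two_ch(bwd(from_two_ch(g)))))
}

# magnitude of a 2-channel complex node -> H x W x 1
ad_cmagnitude <- function(a, eps = 1e-12) {
  v <- a$value
  m <- sqrt(v[, , 1]^2 + v[, , 2]^2 + eps)
  d <- dim(v)
  out <- array(m, c(d[1], d[2], 1L))
  ad_node(out, list(a), list(function(g) {
    gi <- array(0, d)
    gm <- g[, , 1] / m
    gi[, , 1] <- gm * v[, , 1]
    gi[, , 2] <- gm * v[, , 2]
    gi
  }))
}

## ---- sampling-specific operators -------------------------------------------

# exact-mean rate scaling: multiplicative below the target, complementary
# above, so values stay in [0,1] and mean(out) == target exactly.  Closed
# form with exact gradients.
ad_rate_scale <- function(p, target) {
  v <- p$value
  n <- length(v)
  m <- mean(v)
  if (m <= 0) stop("cannot scale an all-zero probability map to a positive rate")
  if (m >= target) {
    s <- target / m
    ad_node(v * s, list(p), list(function(g) {
      s * g - (target / m^2 / n) * sum(g * v)
    }))
  } else {
    cc <- (1 - target) / (1 - m)
    ad_node(1 - (1 - v) * cc, list(p), list(function(g) {
      cc * g - ((1 - target) / (1 - m)^2 / n) * sum(g * (1 - v))
    }))
  }
}

# straight-through top-n binarization of an H x W x 1 score node.
# Forward: 1 at the n largest scores (ties by row-major index); backward:
# gradients pass through unchanged.
ad_topn_st <- function(scores, n) {
  v <- scores$value
  sel <- topn_select(matrix(v, dim(v)[1], dim(v)[2]), n)
  out <- array(sel, dim(v))
  ad_node(out, list(scores), list(function(g) g))
}

# plain top-n selection on a matrix; ties broken by row-major order
topn_select <- function(m, n) {
  stopifnot(n >= 0, n <= length(m))
  out <- matrix(0, nrow(m), ncol(m))
  if (n == 0) return(out)
  rm_order <- order(as.vector(t(m)), decreasing = TRUE)  # row-major tie-break
  # translate row-major positions back to column-major indices
  nr <- nrow(m); nc <- ncol(m)
  rowm <- rm_order - 1L
  ri <- rowm %/% nc + 1L
  ci <- rowm %% nc + 1L
  idx <- (ci - 1L) * nr + ri
  out[idx[seq_len(n)]] <- 1
  out
}

# detach: value flows, gradient is cut
ad_detach <- function(a) ad_const(a$value)

## ---- optimiser -------------------------------------------------------------

#' Adam optimiser state for a flat list of parameter nodes
#' @keywords internal
adam_init <- function(params, lr = 5e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  flat <- ad_flatten(params)
  list(
    params = flat,
    m = lapply(flat, function(p) array(0, dim(p$value) %||% length(p$value))),
    v = lapply(flat, function(p) array(0, dim(p$value) %||% length(p$value))),
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L
  )
}

#' @keywords internal
adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    p$value <- p$value - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
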