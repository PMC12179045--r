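# Minimal dense-prediction network engine in base R. Feature maps are
# [H, W, C] numeric arrays processed one sample at a time; convolutions are
# im2col + BLAS matrix products. Only what the U-Net family needs is
# implemented: 3x3 same-padded convolution, 2x2 max pooling, 2x2 stride-2
# transposed convolution, channel-wise normalization with affine
# scale/shift, ReLU, channel concatenation, and 1x1 convolution.

# [H, W, C] -> (H*W) x (9*C) patch matrix, zero padding at the border.
# Compiled kernels; block order is dy = -1,0,1 fastest, then dx.
im2col3 <- function(x) {
  im2col3_cpp(x, dim(x)[1], dim(x)[2], dim(x)[3])
}

# adjoint of im2col3: scatter-add a (H*W) x (9*C) gradient back to [H, W, C]
col2im3 <- function(g, h, w, c) {
  col2im3_cpp(g, h, w, c)
}

conv3_init <- function(cin, cout) {
  fan_in <- 9 * cin
  list(W = matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
       b = numeric(cout))
}

conv3_fwd <- function(p, x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  X <- im2col3(x)
  y <- X %*% p$W
  y <- y + rep(p$b, each = nrow(y))
  list(out = array(y, c(h, w, ncol(p$W))), cache = list(X = X, dims = dim(x)))
}

conv3_bwd <- function(p, cache, dout) {
  h <- cache$dims[1]; w <- cache$dims[2]; cin <- cache$dims[3]
  dY <- matrix(dout, h * w, dim(dout)[3])
  dW <- crossprod(cache$X, dY)
  db <- colSums(dY)
  dX <- dY %*% t(p$W)
  list(grads = list(W = dW, b = db), dx = col2im3(dX, h, w, cin))
}

conv1_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

conv1_fwd <- function(p, x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  M <- matrix(x, h * w, dim(x)[3])
  y <- M %*% p$W + rep(p$b, each = h * w)
  list(out = array(y, c(h, w, ncol(p$W))), cache = list(M = M, dims = dim(x)))
}

conv1_bwd <- function(p, cache, dout) {
  h <- cache$dims[1]; w <- cache$dims[2]
  dY <- matrix(dout, h * w, dim(dout)[3])
  list(grads = list(W = crossprod(cache$M, dY), b = colSums(dY)),
       dx = array(dY %*% t(p$W), cache$dims))
}

# 2x2 stride-2 transposed convolution: each input pixel paints a 2x2 block.
tconv_init <- function(cin, cout) {
  fan_in <- cin  # one tap per output pixel
  list(W = array(stats::rnorm(4 * cin * cout, 0, sqrt(2 / fan_in)), c(4, cin, cout)),
       b = numeric(cout))
}

tconv_fwd <- function(p, x) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]; cout <- dim(p$W)[3]
  M <- matrix(x, h * w, cin)
  out <- array(0, c(2 * h, 2 * w, cout))
  k <- 0
  for (a in 0:1) for (b in 0:1) {
    k <- k + 1
    y <- M %*% matrix(p$W[k, , ], cin, cout)
    out[seq(1 + a, 2 * h, 2), seq(1 + b, 2 * w, 2), ] <- array(y, c(h, w, cout))
  }
  out <- out + rep(p$b, each = 4 * h * w)
  list(out = out, cache = list(M = M, dims = dim(x)))
}

tconv_bwd <- function(p, cache, dout) {
  h <- cache$dims[1]; w <- cache$dims[2]; cin <- cache$dims[3]
  cout <- dim(p$W)[3]
  dW <- array(0, dim(p$W))
  dM <- matrix(0, h * w, cin)
  k <- 0
  for (a in 0:1) for (b in 0:1) {
    k <- k + 1
    dY <- matrix(dout[seq(1 + a, 2 * h, 2), seq(1 + b, 2 * w, 2), , drop = FALSE],
                 h * w, cout)
    dW[k, , ] <- crossprod(cache$M, dY)
    dM <- dM + dY %*% t(matrix(p$W[k, , ], cin, cout))
  }
  db <- apply(dout, 3, sum)
  list(grads = list(W = dW, b = db), dx = array(dM, cache$dims))
}

maxpool_fwd <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; c <- dim(x)[3]
  subs <- list(x[seq(1, h, 2), seq(1, w, 2), , drop = FALSE],
               x[seq(2, h, 2), seq(1, w, 2), , drop = FALSE],
               x[seq(1, h, 2), seq(2, w, 2), , drop = FALSE],
               x[seq(2, h, 2), seq(2, w, 2), , drop = FALSE])
  m <- pmax(subs[[1]], subs[[2]], subs[[3]], subs[[4]])
  list(out = m, cache = list(subs = subs, m = m, dims = dim(x)))
}

maxpool_bwd <- function(cache, dout) {
  h <- cache$dims[1]; w <- cache$dims[2]; c <- cache$dims[3]
  dx <- array(0, cache$dims)
  assigned <- array(FALSE, dim(cache$m))
  rows <- list(seq(1, h, 2), seq(2, h, 2), seq(1, h, 2), seq(2, h, 2))
  cols <- list(seq(1, w, 2), seq(1, w, 2), seq(2, w, 2), seq(2, w, 2))
  for (k in 1:4) {
    sel <- (cache$subs[[k]] == cache$m) & !assigned  # ties: first in fixed order
    assigned <- assigned | sel
    g <- dout * sel
    dx[rows[[k]], cols[[k]], ] <- g
  }
  dx
}

# Channel-wise normalization with affine scale/shift, statistics computed
# over the spatial extent of each sample (instance-style; see vignette).
norm_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))

norm_fwd <- function(p, x, eps = 1e-5) {
  h <- dim(x)[1]; w <- dim(x)[2]; c <- dim(x)[3]
  M <- matrix(x, h * w, c)
  n <- h * w
  mu <- colMeans(M)
  xc <- M - rep(mu, each = n)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = n)
  y <- xhat * rep(p$gamma, each = n) + rep(p$beta, each = n)
  list(out = array(y, dim(x)),
       cache = list(xhat = xhat, istd = istd, dims = dim(x)))
}

norm_bwd <- function(p, cache, dout) {
  h <- cache$dims[1]; w <- cache$dims[2]; c <- cache$dims[3]
  n <- h * w
  dY <- matrix(dout, n, c)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(p$gamma, each = n)
  t1 <- dxhat - rep(colMeans(dxhat), each = n)
  t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)
  dX <- (t1 - t2) * rep(cache$istd, each = n)
  list(grads = list(gamma = dgamma, beta = dbeta), dx = array(dX, cache$dims))
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dout) dout * cache

# ---- parameter flattening (fixed depth-first order) and Adam ----

flatten_params <- function(p) {
  out <- list()
  walk <- function(x) {
    if (is.list(x)) {
      for (el in x) walk(el)
    } else {
      out[[length(out) + 1]] <<- x
    }
  }
  walk(p)
  out
}

unflatten_params <- function(skeleton, flat) {
  i <- 0
  rebuild <- function(x) {
    if (is.list(x)) {
      lapply(x, rebuild)
    } else {
      i <<- i + 1
      out <- flat[[i]]
      if (!is.null(dim(x))) dim(out) <- dim(x)
      out
    }
  }
  rebuild(skeleton)
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(flat)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    flat[[i]] <- flat[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = flat, state = state)
}
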