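# Minimal convolutional-network primitives.
#
# There is no deep-learning framework in the package's dependency set, so the
# few layer types the super-resolution model needs (3x3 convolutions, leaky
# ReLU, nearest-neighbour x2 upsampling) are implemented directly on R
# arrays: convolutions lower to im2col matrices and a single BLAS matrix
# product, and every layer has an explicit backward pass. Feature maps are
# 3D arrays (height, width, channels); weights are k x k x cin x cout arrays
# flattened to (k*k*cin) x cout matrices with the kernel row index fastest.

nn_pad <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

nn_im2col <- function(xp, k, stride, ho, wo) {
  cin <- dim(xp)[3]
  cols <- matrix(0, ho * wo, k * k * cin)
  ri <- seq.int(1L, by = stride, length.out = ho)
  ci <- seq.int(1L, by = stride, length.out = wo)
  j <- 0L
  for (cc in seq_len(cin)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    j <- j + 1L
    cols[, j] <- xp[ri + ki - 1L, ci + kj - 1L, cc]
  }
  cols
}

nn_conv_fwd <- function(x, W, b, stride = 1L, pad = 1L) {
  d <- dim(x)
  k <- dim(W)[1]
  cout <- dim(W)[4]
  xp <- nn_pad(x, pad)
  ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  cols <- nn_im2col(xp, k, stride, ho, wo)
  Wm <- matrix(W, ncol = cout)
  out_m <- cols %*% Wm
  out_m <- sweep(out_m, 2, b, "+")
  list(out = array(out_m, c(ho, wo, cout)),
       cache = list(cols = cols, W = W, dims = d, k = k, stride = stride,
                    pad = pad, ho = ho, wo = wo))
}

nn_conv_bwd <- function(dout, cache, need_dx = TRUE) {
  k <- cache$k; d <- cache$dims
  cout <- dim(cache$W)[4]
  dout_m <- matrix(dout, ncol = cout)
  dW <- array(crossprod(cache$cols, dout_m), dim(cache$W))
  db <- colSums(dout_m)
  dx <- NULL
  if (need_dx) {
    dcols <- tcrossprod(dout_m, matrix(cache$W, ncol = cout))
    pad <- cache$pad; stride <- cache$stride
    dxp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
    ri <- seq.int(1L, by = stride, length.out = cache$ho)
    ci <- seq.int(1L, by = stride, length.out = cache$wo)
    j <- 0L
    for (cc in seq_len(d[3])) for (kj in seq_len(k)) for (ki in seq_len(k)) {
      j <- j + 1L
      dxp[ri + ki - 1L, ci + kj - 1L, cc] <-
        dxp[ri + ki - 1L, ci + kj - 1L, cc] +
        matrix(dcols[, j], cache$ho, cache$wo)
    }
    dx <- dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE]
  }
  list(dW = dW, db = db, dx = dx)
}

nn_lrelu_fwd <- function(x, slope = 0.2) {
  mask <- x > 0
  list(out = x * (mask + slope * !mask), cache = list(mask = mask,
                                                      slope = slope))
}

nn_lrelu_bwd <- function(dout, cache) {
  dout * (cache$mask + cache$slope * !cache$mask)
}

nn_up2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

nn_up2_bwd <- function(dout) {
  d <- dim(dout)
  o <- seq.int(1L, d[1], by = 2L)
  e <- seq.int(2L, d[1], by = 2L)
  oc <- seq.int(1L, d[2], by = 2L)
  ec <- seq.int(2L, d[2], by = 2L)
  dout[o, oc, , drop = FALSE] + dout[e, oc, , drop = FALSE] +
    dout[o, ec, , drop = FALSE] + dout[e, ec, , drop = FALSE]
}

# He-style initialisation, optionally scaled (residual convs use gain < 1)
nn_init_conv <- function(k, cin, cout, gain = 1) {
  sd <- gain * sqrt(2 / (k * k * cin))
  list(W = array(stats::rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout)),
       b = rep(0, cout))
}

# Adam optimizer over a flat named list of arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
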