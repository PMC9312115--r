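# Native neural-network primitives.
#
# Minimal set of layers needed by the segmentation U-net and the patch
# auto-encoder: same-padding 3x3/1x1 convolution (im2col + BLAS matmul), 2x2
# max pooling, 2x2-stride-2 and 3x3-stride-2 transposed convolution, batch
# normalization, dense layers, ReLU/sigmoid, l2 embedding normalization, and
# Adam. Forward passes return caches consumed by the matching hand-written
# backward passes; everything is vectorized R so the heavy lifting is a
# handful of large matrix products.
#
# Layout: network tensors are numeric arrays [H, W, N, C] (batch before
# channels). With this layout an [H, W, N, C] slice flattens directly to the
# (H*W*N) x C matrices the BLAS products consume, so no axis permutation is
# needed anywhere in the conv/pool path. Public package interfaces use the
# conventional [H, W, C, N]; conversion happens once at network entry/exit
# via nc_in()/nc_out().

nc_in <- function(x) aperm(x, c(1, 2, 4, 3))   # [H,W,C,N] -> [H,W,N,C]
nc_out <- function(x) aperm(x, c(1, 2, 4, 3))  # inverse

nn_pad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

# shifted views of x for a k x k same-padding convolution: list of k*k
# matrices (H*W*N) x C, in offset order (ki fastest, then kj). Gathers are
# 2-D integer row subsets of the flattened padded array, which R executes
# far faster than 4-D range slices.
nn_slabs <- function(x, k) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[3]; ch <- d[4]
  p <- (k - 1L) %/% 2L
  xp <- nn_pad(x, p)
  hp <- h + 2L * p
  dim(xp) <- c(hp * (w + 2L * p), n * ch)
  base_r <- seq_len(h); base_c <- seq_len(w)
  slabs <- vector("list", k * k)
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    rows <- rep(ki - 1L + base_r, times = w) +
      rep((kj - 2L + base_c) * hp, each = h)
    s <- xp[rows, , drop = FALSE]
    dim(s) <- c(h * w * n, ch)
    slabs[[(kj - 1L) * k + ki]] <- s
  }
  slabs
}

# convolution core: y = sum over offsets of slab %*% W_block, never
# materializing the full im2col matrix
nn_conv_core <- function(x, W, k) {
  d <- dim(x); ch <- d[4]
  cout <- ncol(W)
  slabs <- nn_slabs(x, k)
  y <- NULL
  for (o in seq_len(k * k)) {
    t <- slabs[[o]] %*% W[(o - 1L) * ch + seq_len(ch), , drop = FALSE]
    y <- if (is.null(y)) t else y + t
  }
  list(y = y, slabs = slabs)
}

# kernel for the input-gradient pass: spatially flipped, in/out channels
# swapped; (k*k*Cin) x Cout  ->  (k*k*Cout) x Cin
nn_rotate_kernel <- function(W, k, cin) {
  cout <- ncol(W)
  Wa <- array(W, dim = c(cin, k, k, cout))        # column order: cin, ki, kj
  Wa <- Wa[, k:1, k:1, , drop = FALSE]            # spatial flip
  Wt <- aperm(Wa, c(4, 2, 3, 1))                  # -> cout, ki, kj, cin
  dim(Wt) <- c(cout * k * k, cin)
  Wt
}

# y[H,W,N,Cout] from x[H,W,N,Cin]; W is (k*k*Cin) x Cout
conv_forward <- function(x, W, b, k) {
  d <- dim(x)
  co <- nn_conv_core(x, W, k)
  y <- sweep(co$y, 2L, b, "+")
  dim(y) <- c(d[1], d[2], d[3], ncol(W))
  list(y = y, slabs = co$slabs, xdim = d, k = k)
}

conv_backward <- function(dy, cache, W, need_dx = TRUE) {
  d <- cache$xdim; ch <- d[4]; k <- cache$k
  dym <- dy
  dim(dym) <- c(d[1] * d[2] * d[3], ncol(W))
  dW <- do.call(rbind, lapply(cache$slabs, function(s) crossprod(s, dym)))
  db <- colSums(dym)
  dx <- NULL
  if (need_dx) {
    # input gradient = same-padding convolution of dy with the rotated kernel
    dim(dym) <- c(d[1], d[2], d[3], ncol(W))
    dx <- nn_conv_core(dym, nn_rotate_kernel(W, k, ch), k)$y
    dim(dx) <- d
  }
  list(dW = dW, db = db, dx = dx)
}

maxpool_forward <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]
  or <- seq(1L, h, 2L); er <- seq(2L, h, 2L)
  oc <- seq(1L, w, 2L); ec <- seq(2L, w, 2L)
  q <- list(x[or, oc, , , drop = FALSE], x[er, oc, , , drop = FALSE],
            x[or, ec, , , drop = FALSE], x[er, ec, , , drop = FALSE])
  y <- pmax(q[[1]], q[[2]], q[[3]], q[[4]])
  idx <- array(4L, dim = dim(y))
  idx[q[[3]] == y] <- 3L
  idx[q[[2]] == y] <- 2L
  idx[q[[1]] == y] <- 1L   # ties resolve to the first quadrant
  list(y = y, idx = idx, xdim = d)
}

maxpool_backward <- function(dy, cache) {
  d <- cache$xdim
  dx <- array(0, dim = d)
  or <- seq(1L, d[1], 2L); er <- seq(2L, d[1], 2L)
  oc <- seq(1L, d[2], 2L); ec <- seq(2L, d[2], 2L)
  sel <- list(list(or, oc), list(er, oc), list(or, ec), list(er, ec))
  for (qq in 1:4) {
    g <- dy * (cache$idx == qq)
    dx[sel[[qq]][[1]], sel[[qq]][[2]], , ] <-
      dx[sel[[qq]][[1]], sel[[qq]][[2]], , , drop = FALSE] + g
  }
  dx
}

# 2x2 stride-2 transposed convolution: each input pixel paints one 2x2 output
# block; W is Cin x (4*Cout), quadrant order (0,0),(1,0),(0,1),(1,1)
tconv2_forward <- function(x, W, b) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[3]; cin <- d[4]
  cout <- ncol(W) %/% 4L
  xm <- x; dim(xm) <- c(h * w * n, cin)
  ym <- xm %*% W
  out <- array(0, dim = c(2L * h, 2L * w, n, cout))
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (qq in 1:4) {
    s <- ym[, (qq - 1L) * cout + seq_len(cout), drop = FALSE]
    dim(s) <- c(h, w, n, cout)
    out[seq(1L, 2L * h, 2L) + offs[[qq]][1], seq(1L, 2L * w, 2L) + offs[[qq]][2], , ] <- s
  }
  out <- sweep(out, 4L, b, "+")
  list(y = out, xm = xm, xdim = d)
}

tconv2_backward <- function(dy, cache, W) {
  d <- cache$xdim; h <- d[1]; w <- d[2]; n <- d[3]; cin <- d[4]
  cout <- ncol(W) %/% 4L
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  dym <- matrix(0, h * w * n, 4L * cout)
  for (qq in 1:4) {
    s <- dy[seq(1L, 2L * h, 2L) + offs[[qq]][1],
            seq(1L, 2L * w, 2L) + offs[[qq]][2], , , drop = FALSE]
    dim(s) <- c(h * w * n, cout)
    dym[, (qq - 1L) * cout + seq_len(cout)] <- s
  }
  dW <- crossprod(cache$xm, dym)
  db <- apply(dy, 4L, sum)
  dxm <- dym %*% t(W)
  dim(dxm) <- c(h, w, n, cin)
  list(dW = dW, db = db, dx = dxm)
}

# 3x3 stride-2 transposed convolution realized as zero-upsampling followed by
# a same-padding 3x3 convolution (kernel flip is immaterial for learned W)
tconv3_forward <- function(x, W, b) {
  d <- dim(x)
  up <- array(0, dim = c(2L * d[1], 2L * d[2], d[3], d[4]))
  up[seq(1L, 2L * d[1], 2L), seq(1L, 2L * d[2], 2L), , ] <- x
  cv <- conv_forward(up, W, b, 3L)
  cv$orig_dim <- d
  cv
}

tconv3_backward <- function(dy, cache, W) {
  g <- conv_backward(dy, cache, W)
  d <- cache$orig_dim
  g$dx <- g$dx[seq(1L, 2L * d[1], 2L), seq(1L, 2L * d[2], 2L), , , drop = FALSE]
  g
}

bn_forward <- function(x, gamma, beta, state, training = TRUE,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(x); ch <- d[4]
  xm <- x; dim(xm) <- c(d[1] * d[2] * d[3], ch)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2L, mu)^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
  } else {
    mu <- state$mean; va <- state$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, istd, "*")
  ym <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  dim(ym) <- d
  list(y = ym, xhat = xhat, istd = istd, xdim = d, state = state)
}

bn_backward <- function(dy, cache, gamma) {
  d <- cache$xdim; ch <- d[4]
  m <- d[1] * d[2] * d[3]
  dym <- dy; dim(dym) <- c(m, ch)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, "*")
  t1 <- sweep(dxhat, 2L, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
  dxm <- sweep(t1 - t2, 2L, cache$istd, "*")
  dim(dxm) <- d
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}

dense_forward <- function(x, W, b) {
  list(y = sweep(x %*% W, 2L, b, "+"), x = x)
}

dense_backward <- function(dy, cache, W) {
  list(dW = crossprod(cache$x, dy), db = colSums(dy), dx = dy %*% t(W))
}

relu <- function(x) { x[x < 0] <- 0; x }
relu_bwd <- function(dy, y) dy * (y > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# rows of x normalized to unit l2 norm (embedding hypersphere)
l2norm_forward <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm <- pmax(nrm, 1e-12)
  list(y = x / nrm, nrm = nrm)
}

l2norm_backward <- function(dy, y, nrm) {
  (dy - y * rowSums(dy * y)) / nrm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# He-normal initialization for ReLU stacks
he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
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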