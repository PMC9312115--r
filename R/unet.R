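# Stage 1: U-net segmentation of the muscle region inside the fascia lata.

#' U-net configuration
#'
#' @param in_channels Input channels: 2 (T2 + PD), 1 (T2 or PD alone) or 17
#'   (raw echo stack).
#' @param base_filters Feature channels at the first level, doubling per
#'   level. The reference configuration uses 64; desk-scale synthetic
#'   training uses far fewer.
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param augmentation_factor Total images per original slice after geometric
#'   augmentation (1 = no augmentation).
#' @param input_size Spatial input side length; must be divisible by 16
#'   (four 2x2 poolings across the five resolution levels).
#' @param seed Integer seed governing initialization, augmentation and
#'   batch shuffling.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 2L, base_filters = 64L, lr = 0.001,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        batch_size = 8L, epochs = 100L,
                        augmentation_factor = 10L, input_size = 128L,
                        seed = 1L) {
  in_channels <- as.integer(in_channels)
  if (!in_channels %in% c(1L, 2L, 17L)) {
    stop("`in_channels` must be 1, 2 or 17", call. = FALSE)
  }
  if (as.integer(input_size) %% 16L != 0L) {
    stop("`input_size` must be divisible by 16", call. = FALSE)
  }
  structure(list(in_channels = in_channels, levels = 5L,
                 base_filters = as.integer(base_filters), lr = lr,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 augmentation_factor = as.integer(augmentation_factor),
                 input_size = as.integer(input_size),
                 seed = as.integer(seed)),
            class = "unet_config")
}

#' Build an untrained U-net segmentation model
#'
#' Five resolution levels: each encoder level applies two 3x3 convolutions
#' with ReLU (channels doubling after every 2x2/stride-2 max pooling), the
#' symmetric decoder upsamples with 2x2/stride-2 transposed convolutions,
#' concatenates the skip connection and applies two 3x3 convolutions + ReLU,
#' and a final 1x1 convolution with sigmoid yields the single-channel muscle
#' probability map at the input resolution. Convolutions use same-padding so
#' the output grid equals the input grid. Weights are He-initialized
#' deterministically from `config$seed`.
#'
#' @param config A [unet_config()].
#' @return An object of class `unet_model` with `params` and `config`.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  bf <- config$base_filters
  params <- list()
  with_seed(config$seed, {
    cin <- config$in_channels
    for (l in 1:5) {
      cout <- bf * 2L^(l - 1L)
      params[[sprintf("enc%d_c1_W", l)]] <- he_init(9L * cin, cout, 9L * cin)
      params[[sprintf("enc%d_c1_b", l)]] <- rep(0, cout)
      params[[sprintf("enc%d_c2_W", l)]] <- he_init(9L * cout, cout, 9L * cout)
      params[[sprintf("enc%d_c2_b", l)]] <- rep(0, cout)
      cin <- cout
    }
    for (l in 4:1) {
      cup <- bf * 2L^l          # channels arriving from below
      cout <- bf * 2L^(l - 1L)
      params[[sprintf("up%d_W", l)]] <- he_init(cup, 4L * cout, cup)
      params[[sprintf("up%d_b", l)]] <- rep(0, cout)
      params[[sprintf("dec%d_c1_W", l)]] <- he_init(9L * 2L * cout, cout, 9L * 2L * cout)
      params[[sprintf("dec%d_c1_b", l)]] <- rep(0, cout)
      params[[sprintf("dec%d_c2_W", l)]] <- he_init(9L * cout, cout, 9L * cout)
      params[[sprintf("dec%d_c2_b", l)]] <- rep(0, cout)
    }
    params[["final_W"]] <- he_init(bf, 1L, bf)
    params[["final_b"]] <- 0
  })
  structure(list(params = params, config = config, loss_history = NULL),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("unet_model: %d input channels, base %d filters, %s parameters%s\n",
              x$config$in_channels, x$config$base_filters, format(np, big.mark = ","),
              if (is.null(x$loss_history)) " (untrained)" else
                sprintf(", trained %d epochs", length(x$loss_history))))
  invisible(x)
}

# forward pass on an internal-layout [H,W,N,C] tensor; returns probability
# map [H,W,N,1] and caches for backprop
unet_forward <- function(params, x, keep_cache = TRUE) {
  cache <- list()
  enc <- vector("list", 5L)
  cur <- x
  for (l in 1:5) {
    c1 <- conv_forward(cur, params[[sprintf("enc%d_c1_W", l)]],
                       params[[sprintf("enc%d_c1_b", l)]], 3L)
    a1 <- relu(c1$y)
    c2 <- conv_forward(a1, params[[sprintf("enc%d_c2_W", l)]],
                       params[[sprintf("enc%d_c2_b", l)]], 3L)
    a2 <- relu(c2$y)
    enc[[l]] <- a2
    if (keep_cache) cache[[sprintf("enc%d", l)]] <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2)
    if (l < 5L) {
      mp <- maxpool_forward(a2)
      cur <- mp$y
      if (keep_cache) cache[[sprintf("pool%d", l)]] <- mp
    }
  }
  cur <- enc[[5]]
  for (l in 4:1) {
    up <- tconv2_forward(cur, params[[sprintf("up%d_W", l)]],
                         params[[sprintf("up%d_b", l)]])
    cat_ <- abind4(up$y, enc[[l]])
    c1 <- conv_forward(cat_, params[[sprintf("dec%d_c1_W", l)]],
                       params[[sprintf("dec%d_c1_b", l)]], 3L)
    a1 <- relu(c1$y)
    c2 <- conv_forward(a1, params[[sprintf("dec%d_c2_W", l)]],
                       params[[sprintf("dec%d_c2_b", l)]], 3L)
    a2 <- relu(c2$y)
    if (keep_cache) cache[[sprintf("dec%d", l)]] <- list(up = up, c1 = c1, a1 = a1, c2 = c2, a2 = a2)
    cur <- a2
  }
  fin <- conv_forward(cur, params[["final_W"]], params[["final_b"]], 1L)
  prob <- sigmoid(fin$y)
  if (keep_cache) cache$final <- fin
  list(prob = prob, cache = cache)
}

# concatenate two internal-layout [H,W,N,C] arrays along the channel axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# backward pass from d(loss)/d(prob); returns gradient list matching params
unet_backward <- function(params, fw, dprob) {
  grads <- list()
  prob <- fw$prob
  dlogit <- dprob * prob * (1 - prob)
  g <- conv_backward(dlogit, fw$cache$final, params[["final_W"]])
  grads[["final_W"]] <- g$dW; grads[["final_b"]] <- g$db
  dcur <- g$dx
  for (l in 1:4) {
    dc <- fw$cache[[sprintf("dec%d", l)]]
    d2 <- relu_bwd(dcur, dc$a2)
    g <- conv_backward(d2, dc$c2, params[[sprintf("dec%d_c2_W", l)]])
    grads[[sprintf("dec%d_c2_W", l)]] <- g$dW; grads[[sprintf("dec%d_c2_b", l)]] <- g$db
    d1 <- relu_bwd(g$dx, dc$a1)
    g <- conv_backward(d1, dc$c1, params[[sprintf("dec%d_c1_W", l)]])
    grads[[sprintf("dec%d_c1_W", l)]] <- g$dW; grads[[sprintf("dec%d_c1_b", l)]] <- g$db
    cup <- dim(dc$up$y)[4]
    dup <- g$dx[, , , seq_len(cup), drop = FALSE]
    dskip <- g$dx[, , , cup + seq_len(dim(g$dx)[4] - cup), drop = FALSE]
    g <- tconv2_backward(dup, dc$up, params[[sprintf("up%d_W", l)]])
    grads[[sprintf("up%d_W", l)]] <- g$dW; grads[[sprintf("up%d_b", l)]] <- g$db
    # gradient flowing into encoder level l activation via the skip path
    fw$cache[[sprintf("skipgrad%d", l)]] <- dskip
    dcur <- g$dx
  }
  # encoder backward, accumulating skip gradients
  denc <- dcur  # gradient into enc5 activation
  for (l in 5:1) {
    ec <- fw$cache[[sprintf("enc%d", l)]]
    if (l < 5L) {
      dpool <- maxpool_backward(denc, fw$cache[[sprintf("pool%d", l)]])
      dtot <- dpool + fw$cache[[sprintf("skipgrad%d", l)]]
    } else {
      dtot <- denc
    }
    d2 <- relu_bwd(dtot, ec$a2)
    g <- conv_backward(d2, ec$c2, params[[sprintf("enc%d_c2_W", l)]])
    grads[[sprintf("enc%d_c2_W", l)]] <- g$dW; grads[[sprintf("enc%d_c2_b", l)]] <- g$db
    d1 <- relu_bwd(g$dx, ec$a1)
    g <- conv_backward(d1, ec$c1, params[[sprintf("enc%d_c1_W", l)]],
                       need_dx = l > 1L)
    grads[[sprintf("enc%d_c1_W", l)]] <- g$dW; grads[[sprintf("enc%d_c1_b", l)]] <- g$db
    denc <- g$dx
  }
  grads
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * gt) + eps) / (sum(pred) + sum(gt) + eps)`, computed
#' per image and averaged over the batch; differentiable in `pred`.
#'
#' @param pred Probability image(s) in `[0, 1]`: a matrix or `[H,W,1,N]`.
#' @param gt Binary ground truth of matching shape.
#' @param eps Smoothing constant (default 1e-6).
#' @return Scalar loss.
#' @export
soft_dice_loss <- function(pred, gt, eps = 1e-6) {
  if (is.matrix(pred)) pred <- array(pred, dim = c(dim(pred), 1L, 1L))
  if (is.matrix(gt)) gt <- array(gt, dim = c(dim(gt), 1L, 1L))
  if (!identical(dim(pred), dim(gt))) stop("`pred` and `gt` shapes differ", call. = FALSE)
  n <- dim(pred)[4]
  tot <- 0
  for (i in seq_len(n)) {
    p <- pred[, , , i]; g <- gt[, , , i]
    tot <- tot + 1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
  }
  tot / n
}

# internal-layout ([H,W,N,1]) soft Dice loss and gradient used in training
sdice_loss_i <- function(pred, gt, eps = 1e-6) {
  n <- dim(pred)[3]
  tot <- 0
  for (i in seq_len(n)) {
    p <- pred[, , i, ]; g <- gt[, , i, ]
    tot <- tot + 1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
  }
  tot / n
}

sdice_grad_i <- function(pred, gt, eps = 1e-6) {
  n <- dim(pred)[3]
  dp <- array(0, dim = dim(pred))
  for (i in seq_len(n)) {
    p <- pred[, , i, ]; g <- gt[, , i, ]
    num <- 2 * sum(p * g) + eps
    den <- sum(p) + sum(g) + eps
    dp[, , i, ] <- -(2 * g * den - num) / den^2 / n
  }
  dp
}

#' Geometric augmentation of an image/mask pair
#'
#' Draws `n_augment` geometric transforms: in-plane shift within +/-20% of
#' the image size per axis, isotropic zoom in `[0.9, 1.3]`, rotation in
#' `[0, 30]` degrees and independent horizontal/vertical flips. The identical
#' transform is applied to the image (bilinear) and the mask
#' (nearest-neighbor). The first returned pair is the untransformed original
#' so an augmentation factor of `k` multiplies the dataset by exactly `k`.
#'
#' @param image Array `H x W x C` (or matrix).
#' @param mask Binary matrix `H x W`.
#' @param n_augment Number of pairs to return (>= 1).
#' @param seed Integer seed; the set is bit-reproducible.
#' @param shift,zoom,rotation Ranges of the transform parameters.
#' @return List with `images` (`H x W x C x n_augment`) and `masks`
#'   (`H x W x n_augment`, binary).
#' @export
augment_batch <- function(image, mask, n_augment, seed = 1L,
                          shift = 0.2, zoom = c(0.9, 1.3), rotation = c(0, 30)) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  h <- dim(image)[1]; w <- dim(image)[2]; nc <- dim(image)[3]
  imgs <- array(0, dim = c(h, w, nc, n_augment))
  msks <- array(0, dim = c(h, w, n_augment))
  imgs[, , , 1L] <- image
  msks[, , 1L] <- mask
  if (n_augment > 1L) with_seed(seed, {
    for (a in 2:n_augment) {
      th <- stats::runif(1, rotation[1], rotation[2]) * pi / 180
      z <- stats::runif(1, zoom[1], zoom[2])
      dr <- stats::runif(1, -shift, shift) * h
      dc <- stats::runif(1, -shift, shift) * w
      fh <- stats::runif(1) < 0.5
      fv <- stats::runif(1) < 0.5
      wi <- warp_affine(image, th, z, dr, dc, fh, fv, bilinear = TRUE)
      wm <- warp_affine(array(mask, dim = c(h, w, 1L)), th, z, dr, dc, fh, fv,
                        bilinear = FALSE)
      imgs[, , , a] <- wi
      msks[, , a] <- wm[, , 1L] > 0.5
    }
  })
  list(images = imgs, masks = msks)
}

# center-anchored affine warp (rotation, isotropic zoom, shift, flips);
# inverse mapping with bilinear or nearest sampling, zero outside
warp_affine <- function(img, theta, zoom, dr, dc, flip_h, flip_v, bilinear = TRUE) {
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  ctr_r <- (h + 1) / 2; ctr_c <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w) - ctr_r
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - ctr_c
  # invert: output pixel -> source location
  r0 <- (cos(theta) * (rr - dr) + sin(theta) * (cc - dc)) / zoom
  c0 <- (-sin(theta) * (rr - dr) + cos(theta) * (cc - dc)) / zoom
  if (flip_v) r0 <- -r0
  if (flip_h) c0 <- -c0
  sr <- r0 + ctr_r; sc <- c0 + ctr_c
  out <- array(0, dim = dim(img))
  if (bilinear) {
    fr <- floor(sr); fc <- floor(sc)
    wr <- sr - fr; wc <- sc - fc
    for (k in seq_len(nc)) {
      ch <- img[, , k]
      gv <- function(r, c) {
        ok <- r >= 1 & r <= h & c >= 1 & c <= w
        v <- numeric(length(r))
        v[ok] <- ch[cbind(r[ok], c[ok])]
        v
      }
      v <- (1 - wr) * (1 - wc) * gv(fr, fc) + wr * (1 - wc) * gv(fr + 1, fc) +
        (1 - wr) * wc * gv(fr, fc + 1) + wr * wc * gv(fr + 1, fc + 1)
      out[, , k] <- matrix(v, h, w)
    }
  } else {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    for (k in seq_len(nc)) {
      ch <- img[, , k]
      v <- numeric(h * w)
      v[ok] <- ch[cbind(ri[ok], ci[ok])]
      out[, , k] <- matrix(v, h, w)
    }
  }
  out
}

#' Train the stage-1 muscle segmentation U-net
#'
#' Augments the training slices geometrically, then optimizes the soft Dice
#' loss with Adam over shuffled mini-batches. The best parameter set by epoch
#' training loss is retained (no validation split). Deterministic given
#' `config$seed`.
#'
#' @param images Array `H x W x C x N` of preprocessed input slices.
#' @param masks Array `H x W x N` of binary muscle-region masks.
#' @param config A [unet_config()].
#' @param verbose Print per-epoch loss.
#' @return A trained `unet_model` with `loss_history` (per-epoch mean loss).
#' @export
train_stage1 <- function(images, masks, config, verbose = FALSE) {
  stopifnot(inherits(config, "unet_config"))
  if (length(dim(images)) != 4L) stop("`images` must be H x W x C x N", call. = FALSE)
  n <- dim(images)[4]
  if (n < 2L) stop("need at least 2 training slices", call. = FALSE)
  if (dim(images)[3] != config$in_channels) {
    stop("`images` channel count does not match `config$in_channels`", call. = FALSE)
  }
  h <- dim(images)[1]; w <- dim(images)[2]
  af <- config$augmentation_factor
  model <- build_unet(config)
  params <- model$params
  state <- adam_init(params)
  X <- array(0, dim = c(h, w, config$in_channels, n * af))
  M <- array(0, dim = c(h, w, n * af))
  for (i in seq_len(n)) {
    img_i <- array(images[, , , i], dim = c(h, w, config$in_channels))
    aug <- augment_batch(img_i, masks[, , i], af, seed = child_seed(config$seed, 50L + i))
    X[, , , (i - 1L) * af + seq_len(af)] <- aug$images
    M[, , (i - 1L) * af + seq_len(af)] <- aug$masks
  }
  ntot <- n * af
  Xi <- nc_in(X)   # internal layout [H,W,N,C]
  bs <- config$batch_size
  hist <- numeric(config$epochs)
  best <- list(loss = Inf, params = params)
  with_seed(child_seed(config$seed, 99L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(ntot)
      ep_loss <- 0; nb <- 0L
      for (s in seq(1L, ntot, by = bs)) {
        sel <- ord[s:min(s + bs - 1L, ntot)]
        xb <- Xi[, , sel, , drop = FALSE]
        mb <- array(M[, , sel], dim = c(h, w, length(sel), 1L))
        fw <- unet_forward(params, xb)
        loss <- sdice_loss_i(fw$prob, mb)
        dprob <- sdice_grad_i(fw$prob, mb)
        grads <- unet_backward(params, fw, dprob)
        upd <- adam_step(params, grads, state, lr = config$lr,
                         beta1 = config$beta1, beta2 = config$beta2,
                         eps = config$eps)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      hist[ep] <- ep_loss / nb
      if (hist[ep] < best$loss) best <- list(loss = hist[ep], params = params)
      if (verbose) message(sprintf("epoch %3d  soft-dice loss %.4f", ep, hist[ep]))
    }
  })
  model$params <- best$params
  model$loss_history <- hist
  model
}

#' Predict the muscle-region mask for one slice
#'
#' Runs the trained U-net, thresholds the sigmoid output at 0.5, keeps the
#' largest connected component, fills its holes, and re-punches interior
#' negative components larger than `min_hole_px` pixels (the bone exclusions
#' inside the muscle compartment).
#'
#' @param model A trained `unet_model`.
#' @param input Array `H x W x C` matching the training channel
#'   configuration (or a matrix for 1-channel models).
#' @param min_hole_px Minimum interior hole size to preserve (default 10).
#' @return Logical `H x W` muscle mask with attribute
#'   `provenance = "predicted"`.
#' @export
predict_muscle_mask <- function(model, input, min_hole_px = 10L) {
  stopifnot(inherits(model, "unet_model"))
  if (is.matrix(input)) input <- array(input, dim = c(dim(input), 1L))
  if (dim(input)[3] != model$config$in_channels) {
    stop("input channel count does not match the trained configuration", call. = FALSE)
  }
  d <- dim(input)
  x <- array(input, dim = c(d[1], d[2], 1L, d[3]))  # [H,W,C] == [H,W,1,C] layout
  fw <- unet_forward(model$params, x, keep_cache = FALSE)
  prob <- fw$prob[, , 1L, 1L]
  m <- prob > 0.5
  if (!any(m)) {
    return(structure(m, provenance = "predicted"))
  }
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  tab <- tabulate(as.integer(lab[lab > 0]))
  core <- as.matrix(lab) == which.max(tab)
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(core * 1))) > 0
  holes <- filled & !core
  if (any(holes)) {
    hl <- EBImage::bwlabel(EBImage::Image(holes * 1))
    ht <- tabulate(as.integer(hl[hl > 0]))
    keep <- which(ht >= min_hole_px)   # large holes are anatomy (bone), keep open
    punch <- as.matrix(hl) %in% keep
    filled[matrix(punch, nrow(filled))] <- FALSE
  }
  structure(filled, provenance = "predicted")
}
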