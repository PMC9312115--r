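# Stage 2 representation learning: deep convolutional auto-encoder (DCAE)
# trained on 16x16x2 T2/PD patches, optionally with a triplet-loss constraint
# on the embedding (DCAETL) or a deep-embedded-clustering objective (DCAE_DC).
#
# Encoder: two blocks of [3x3 conv + ReLU, 2x2 max pool, batch-norm] with 32
# and 64 feature maps, flattened to 1024 units, a dense layer to the latent
# space and l2 normalization constraining embeddings to the hypersphere.
# Decoder: dense back to 1024, reshaped to 4x4x64, then two 3x3 stride-2
# transposed convolutions (32 filters, then 2 output channels).

#' DCAE training configuration
#'
#' @param latent_dim Embedding dimension (default 16; the architecture fixes
#'   the 1024-unit flatten, the embedded dimension is a free design knob).
#' @param margin Triplet-loss margin alpha (default 1).
#' @param beta,lambda Combined-loss weights for the triplet and
#'   reconstruction terms (defaults 1/2 and 1/6).
#' @param batch_size Triplets (or patches) per step (default 256).
#' @param epochs Training epochs (default 100).
#' @param lr Adam learning rate (Adam defaults throughout).
#' @param encoder_filters Feature maps of the two encoder blocks.
#' @param seed Integer seed for initialization and sampling.
#' @return An object of class `dcae_config`.
#' @export
dcae_config <- function(latent_dim = 16L, margin = 1, beta = 1 / 2,
                        lambda = 1 / 6, batch_size = 256L, epochs = 100L,
                        lr = 1e-3, encoder_filters = c(32L, 64L), seed = 1L) {
  if (margin <= 0) stop("`margin` must be positive", call. = FALSE)
  if (beta < 0 || lambda < 0) stop("loss weights must be non-negative", call. = FALSE)
  structure(list(latent_dim = as.integer(latent_dim), margin = margin,
                 beta = beta, lambda = lambda,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 encoder_filters = as.integer(encoder_filters),
                 seed = as.integer(seed)),
            class = "dcae_config")
}

dcae_init <- function(config) {
  f1 <- config$encoder_filters[1]; f2 <- config$encoder_filters[2]
  flat <- 4L * 4L * f2
  params <- list()
  with_seed(config$seed, {
    params$c1_W <- he_init(9L * 2L, f1, 9L * 2L); params$c1_b <- rep(0, f1)
    params$bn1_g <- rep(1, f1); params$bn1_b <- rep(0, f1)
    params$c2_W <- he_init(9L * f1, f2, 9L * f1); params$c2_b <- rep(0, f2)
    params$bn2_g <- rep(1, f2); params$bn2_b <- rep(0, f2)
    params$de_W <- he_init(flat, config$latent_dim, flat)
    params$de_b <- rep(0, config$latent_dim)
    params$dd_W <- he_init(config$latent_dim, flat, config$latent_dim)
    params$dd_b <- rep(0, flat)
    params$t1_W <- he_init(9L * f2, f1, 9L * f2); params$t1_b <- rep(0, f1)
    params$t2_W <- he_init(9L * f1, 2L, 9L * f1); params$t2_b <- rep(0, 2L)
  })
  bn <- list(bn1 = list(mean = rep(0, f1), var = rep(1, f1)),
             bn2 = list(mean = rep(0, f2), var = rep(1, f2)))
  structure(list(params = params, bn = bn, config = config,
                 loss_history = NULL),
            class = "dcae_model")
}

#' @export
print.dcae_model <- function(x, ...) {
  cat(sprintf("dcae_model: latent dim %d, encoder filters %s%s\n",
              x$config$latent_dim,
              paste(x$config$encoder_filters, collapse = "/"),
              if (is.null(x$loss_history)) " (untrained)" else
                sprintf(", trained %d epochs", length(x$loss_history))))
  invisible(x)
}

# full forward pass on an internal-layout [16,16,N,2] batch; training mode
# updates BN running stats (returned)
dcae_forward <- function(params, bn, x, training = TRUE) {
  f2 <- length(params$c2_b)
  n <- dim(x)[3]
  c1 <- conv_forward(x, params$c1_W, params$c1_b, 3L); a1 <- relu(c1$y)
  p1 <- maxpool_forward(a1)
  b1 <- bn_forward(p1$y, params$bn1_g, params$bn1_b, bn$bn1, training)
  c2 <- conv_forward(b1$y, params$c2_W, params$c2_b, 3L); a2 <- relu(c2$y)
  p2 <- maxpool_forward(a2)
  b2 <- bn_forward(p2$y, params$bn2_g, params$bn2_b, bn$bn2, training)
  flat <- t(matrix(aperm(b2$y, c(1, 2, 4, 3)), 16L * f2, n))
  de <- dense_forward(flat, params$de_W, params$de_b)
  l2 <- l2norm_forward(de$y)
  z <- l2$y
  dd <- dense_forward(z, params$dd_W, params$dd_b); ad <- relu(dd$y)
  r <- aperm(array(t(ad), dim = c(4L, 4L, f2, n)), c(1, 2, 4, 3))
  t1 <- tconv3_forward(r, params$t1_W, params$t1_b); at1 <- relu(t1$y)
  t2 <- tconv3_forward(at1, params$t2_W, params$t2_b)
  list(z = z, xhat = t2$y,
       bn = list(bn1 = b1$state, bn2 = b2$state),
       cache = list(c1 = c1, a1 = a1, p1 = p1, b1 = b1, c2 = c2, a2 = a2,
                    p2 = p2, b2 = b2, flat = flat, de = de, l2 = l2,
                    dd = dd, ad = ad, rdim = dim(r), t1 = t1, at1 = at1,
                    t2 = t2))
}

# encoder-only forward in inference mode (no caches, no decoder)
dcae_encode <- function(params, bn, x) {
  f2 <- length(params$c2_b)
  n <- dim(x)[3]
  a1 <- relu(conv_forward(x, params$c1_W, params$c1_b, 3L)$y)
  p1 <- maxpool_forward(a1)$y
  b1 <- bn_forward(p1, params$bn1_g, params$bn1_b, bn$bn1, FALSE)$y
  a2 <- relu(conv_forward(b1, params$c2_W, params$c2_b, 3L)$y)
  p2 <- maxpool_forward(a2)$y
  b2 <- bn_forward(p2, params$bn2_g, params$bn2_b, bn$bn2, FALSE)$y
  flat <- t(matrix(aperm(b2, c(1, 2, 4, 3)), 16L * f2, n))
  l2norm_forward(dense_forward(flat, params$de_W, params$de_b)$y)$y
}

# backward from d(loss)/d(xhat) and an extra gradient injected at z
# (triplet or clustering term); returns gradient list matching params
dcae_backward <- function(params, fw, dxhat, dz_extra = NULL) {
  ca <- fw$cache
  n <- nrow(fw$z)
  grads <- list()
  g <- tconv3_backward(dxhat, ca$t2, params$t2_W)
  grads$t2_W <- g$dW; grads$t2_b <- g$db
  d <- relu_bwd(g$dx, ca$at1)
  g <- tconv3_backward(d, ca$t1, params$t1_W)
  grads$t1_W <- g$dW; grads$t1_b <- g$db
  dr <- g$dx
  dad <- t(matrix(aperm(dr, c(1, 2, 4, 3)), ca$rdim[1] * ca$rdim[2] * ca$rdim[4], n))
  ddd <- relu_bwd(dad, ca$ad)
  g <- dense_backward(ddd, ca$dd, params$dd_W)
  grads$dd_W <- g$dW; grads$dd_b <- g$db
  dz <- g$dx
  if (!is.null(dz_extra)) dz <- dz + dz_extra
  dde <- l2norm_backward(dz, ca$l2$y, ca$l2$nrm)
  g <- dense_backward(dde, ca$de, params$de_W)
  grads$de_W <- g$dW; grads$de_b <- g$db
  dflat <- g$dx
  f2 <- length(params$c2_b)
  db2y <- aperm(array(t(dflat), dim = c(4L, 4L, f2, n)), c(1, 2, 4, 3))
  g <- bn_backward(db2y, ca$b2, params$bn2_g)
  grads$bn2_g <- g$dgamma; grads$bn2_b <- g$dbeta
  d <- maxpool_backward(g$dx, ca$p2)
  d <- relu_bwd(d, ca$a2)
  g <- conv_backward(d, ca$c2, params$c2_W)
  grads$c2_W <- g$dW; grads$c2_b <- g$db
  g2 <- bn_backward(g$dx, ca$b1, params$bn1_g)
  grads$bn1_g <- g2$dgamma; grads$bn1_b <- g2$dbeta
  d <- maxpool_backward(g2$dx, ca$p1)
  d <- relu_bwd(d, ca$a1)
  g <- conv_backward(d, ca$c1, params$c1_W, need_dx = FALSE)
  grads$c1_W <- g$dW; grads$c1_b <- g$db
  grads
}

#' Embed patches with a trained DCAE encoder
#'
#' Runs the encoder in inference mode (batch-norm uses running statistics)
#' and returns the l2-normalized latent vectors.
#'
#' @param model A `dcae_model`.
#' @param patches Array `16 x 16 x 2 x M` (or a single `16 x 16 x 2` patch).
#' @param chunk Patches embedded per block (bounds peak memory).
#' @return Matrix `M x latent_dim` with unit-norm rows.
#' @export
dcae_embed <- function(model, patches, chunk = 512L) {
  if (length(dim(patches)) == 3L) patches <- array(patches, dim = c(dim(patches), 1L))
  m <- dim(patches)[4]
  z <- matrix(0, m, model$config$latent_dim)
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    xb <- nc_in(patches[, , , s:e, drop = FALSE])
    z[s:e, ] <- dcae_encode(model$params, model$bn, xb)
  }
  z
}

#' Triplet loss on latent vectors
#'
#' `sum_i max(0, ||f_a - f_p||^2 - ||f_a - f_n||^2 + margin)` over the batch.
#'
#' @param f_a,f_p,f_n Latent vectors (rows are batch items; plain vectors are
#'   treated as one item).
#' @param margin Margin alpha enforced between positive and negative pairs.
#' @return Scalar loss.
#' @export
triplet_loss <- function(f_a, f_p, f_n, margin = 1) {
  if (is.null(dim(f_a))) { f_a <- rbind(f_a); f_p <- rbind(f_p); f_n <- rbind(f_n) }
  if (!all(dim(f_a) == dim(f_p)) || !all(dim(f_a) == dim(f_n))) {
    stop("latent vectors must share one dimension", call. = FALSE)
  }
  dap <- rowSums((f_a - f_p)^2)
  dan <- rowSums((f_a - f_n)^2)
  sum(pmax(0, dap - dan + margin))
}

# gradients of triplet_loss w.r.t. the three latent matrices
triplet_grads <- function(f_a, f_p, f_n, margin = 1) {
  dap <- rowSums((f_a - f_p)^2)
  dan <- rowSums((f_a - f_n)^2)
  act <- (dap - dan + margin) > 0
  da <- 2 * (f_n - f_p) * act
  dp <- 2 * (f_p - f_a) * act
  dn <- 2 * (f_a - f_n) * act
  list(da = da, dp = dp, dn = dn)
}

# mean-squared reconstruction error over the batch (squared l2 per item);
# public [.,.,C,N] layout for the exported combined_loss
mse_loss <- function(x, xhat) sum((x - xhat)^2) / dim(x)[4]
mse_grad <- function(x, xhat) 2 * (xhat - x) / dim(x)[4]
# internal [.,.,N,C] layout used in the training loops
mse_loss_i <- function(x, xhat) sum((x - xhat)^2) / dim(x)[3]
mse_grad_i <- function(x, xhat) 2 * (xhat - x) / dim(x)[3]

#' Combined DCAETL loss
#'
#' `beta * L_triplet + lambda * (MSE_a + MSE_p + MSE_n)`, with the triplet
#' term summed over the batch and each MSE term the batch-mean squared
#' reconstruction error of its stream.
#'
#' @param f_a,f_p,f_n Latent matrices of the three streams.
#' @param x_a,x_p,x_n Input patch batches (`16 x 16 x 2 x N`).
#' @param xhat_a,xhat_p,xhat_n Reconstructions.
#' @param beta,lambda,margin Loss weights and triplet margin.
#' @return Scalar loss.
#' @export
combined_loss <- function(f_a, f_p, f_n, x_a, x_p, x_n,
                          xhat_a, xhat_p, xhat_n,
                          beta = 1 / 2, lambda = 1 / 6, margin = 1) {
  if (beta < 0 || lambda < 0) stop("loss weights must be non-negative", call. = FALSE)
  beta * triplet_loss(f_a, f_p, f_n, margin) +
    lambda * (mse_loss(x_a, xhat_a) + mse_loss(x_p, xhat_p) + mse_loss(x_n, xhat_n))
}

#' Train the DCAE with the combined triplet + reconstruction loss (DCAETL)
#'
#' Jointly optimizes encoder and decoder on randomly sampled weakly labeled
#' triplets with Adam. Embeddings are l2-normalized by construction.
#'
#' @param patchset A [extract_patches()]/[combine_patch_sets()] result with
#'   both weak-label classes present.
#' @param config A [dcae_config()].
#' @param verbose Print per-epoch loss.
#' @return A trained `dcae_model` with `loss_history`.
#' @export
train_dcaetl <- function(patchset, config = dcae_config(), verbose = FALSE) {
  lab <- patchset$weak_labels
  if (!any(lab == 0L, na.rm = TRUE) || !any(lab == 1L, na.rm = TRUE)) {
    stop("both weak-label classes are required; use train_dcae() for unlabeled data",
         call. = FALSE)
  }
  model <- dcae_init(config)
  params <- model$params; bn <- model$bn
  state <- adam_init(params)
  m <- dim(patchset$patches)[4]
  steps <- max(1L, ceiling(m / config$batch_size))
  hist <- numeric(config$epochs)
  with_seed(child_seed(config$seed, 11L), {
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      for (st in seq_len(steps)) {
        idx <- sample_triplet_indices(lab, min(config$batch_size, m))
        xa <- nc_in(patchset$patches[, , , idx$a, drop = FALSE])
        xp <- nc_in(patchset$patches[, , , idx$p, drop = FALSE])
        xn <- nc_in(patchset$patches[, , , idx$n, drop = FALSE])
        fa <- dcae_forward(params, bn, xa, TRUE); bn <- fa$bn
        fp <- dcae_forward(params, bn, xp, TRUE); bn <- fp$bn
        fn_ <- dcae_forward(params, bn, xn, TRUE); bn <- fn_$bn
        loss <- config$beta * triplet_loss(fa$z, fp$z, fn_$z, config$margin) +
          config$lambda * (mse_loss_i(xa, fa$xhat) + mse_loss_i(xp, fp$xhat) +
                             mse_loss_i(xn, fn_$xhat))
        tg <- triplet_grads(fa$z, fp$z, fn_$z, config$margin)
        ga <- dcae_backward(params, fa, config$lambda * mse_grad_i(xa, fa$xhat),
                            config$beta * tg$da)
        gp <- dcae_backward(params, fp, config$lambda * mse_grad_i(xp, fp$xhat),
                            config$beta * tg$dp)
        gn <- dcae_backward(params, fn_, config$lambda * mse_grad_i(xn, fn_$xhat),
                            config$beta * tg$dn)
        grads <- Map(function(a, b, c) a + b + c, ga, gp, gn)
        upd <- adam_step(params, grads, state, lr = config$lr)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss
      }
      hist[ep] <- ep_loss / steps
      if (verbose) message(sprintf("epoch %3d  combined loss %.4f", ep, hist[ep]))
    }
  })
  model$params <- params; model$bn <- bn; model$loss_history <- hist
  model
}

#' Train the plain DCAE (reconstruction loss only)
#'
#' The comparison baseline: same architecture as [train_dcaetl()] but a
#' single input stream and pure MSE reconstruction loss.
#'
#' @inheritParams train_dcaetl
#' @return A trained `dcae_model`.
#' @export
train_dcae <- function(patchset, config = dcae_config(), verbose = FALSE) {
  model <- dcae_init(config)
  params <- model$params; bn <- model$bn
  state <- adam_init(params)
  m <- dim(patchset$patches)[4]
  steps <- max(1L, ceiling(m / config$batch_size))
  hist <- numeric(config$epochs)
  with_seed(child_seed(config$seed, 13L), {
    for (ep in seq_len(config$epochs)) {
      ep_loss <- 0
      ord <- sample.int(m)
      for (st in seq_len(steps)) {
        sel <- ord[((st - 1L) * config$batch_size + 1L):min(st * config$batch_size, m)]
        xb <- nc_in(patchset$patches[, , , sel, drop = FALSE])
        fw <- dcae_forward(params, bn, xb, TRUE); bn <- fw$bn
        loss <- mse_loss_i(xb, fw$xhat)
        grads <- dcae_backward(params, fw, mse_grad_i(xb, fw$xhat))
        upd <- adam_step(params, grads, state, lr = config$lr)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss
      }
      hist[ep] <- ep_loss / steps
      if (verbose) message(sprintf("epoch %3d  MSE loss %.4f", ep, hist[ep]))
    }
  })
  model$params <- params; model$bn <- bn; model$loss_history <- hist
  model
}
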