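# Auto-encoder losses, embedding contract, training behavior.

test_that("triplet loss matches hand arithmetic", {
  a <- c(1, 0); n2 <- c(1, sqrt(2))           # ||a - n2||^2 = 2
  expect_equal(triplet_loss(a, a, n2, margin = 1), 0)
  expect_equal(triplet_loss(a, a, a, margin = 1), 1)
  p <- a + c(sqrt(0.5), 0); nn <- a + c(1, 0)  # d_ap = 0.5, d_an = 1
  expect_equal(triplet_loss(a, p, nn, margin = 1), 0.5)
  expect_error(triplet_loss(a, c(1, 2, 3), nn), "dimension|share")
})

test_that("combined loss reduces and sums as specified", {
  za <- rbind(c(1, 0)); zp <- rbind(c(1, 0)); zn <- rbind(c(-1, 0))
  x <- array(0.3, c(16, 16, 2, 1))
  # perfect reconstructions + separated embeddings (d_an = 4 > margin) -> 0
  expect_equal(combined_loss(za, zp, zn, x, x, x, x, x, x), 0)
  # beta = 0 leaves the weighted reconstruction stream only
  xh <- x + 1 / sqrt(512)   # unit squared error per patch
  expect_equal(combined_loss(za, zp, zn, x, x, x, xh, xh, xh, beta = 0, lambda = 1 / 6),
               3 / 6, tolerance = 1e-12)
  # unit MSE per stream and unit triplet loss with the default weights -> 1.0
  expect_equal(combined_loss(za, za, za, x, x, x, xh, xh, xh,
                             beta = 1 / 2, lambda = 1 / 6), 0.5 + 0.5,
               tolerance = 1e-12)
  expect_error(combined_loss(za, zp, zn, x, x, x, x, x, x, beta = -1), "non-negative")
})

test_that("embeddings live on the unit hypersphere", {
  enc <- fx_toy_encoder()
  z <- dcae_embed(enc, fx_toy_patches()$patches)
  expect_lt(max(abs(sqrt(rowSums(z^2)) - 1)), 1e-5)
  # single-patch embedding works and is consistent with the batch path
  z1 <- dcae_embed(enc, fx_toy_patches()$patches[, , , 1])
  expect_equal(drop(z1), z[1, ], tolerance = 1e-10)
})

test_that("training separates the classes and reduces the loss", {
  enc <- fx_toy_encoder()
  expect_lt(tail(enc$loss_history, 1), enc$loss_history[1])
  ps <- fx_toy_patches()
  z <- dcae_embed(enc, ps$patches)
  l <- ps$weak_labels
  mu0 <- colMeans(z[l == 0L, ]); mu1 <- colMeans(z[l == 1L, ])
  within <- mean(c(sqrt(rowSums(sweep(z[l == 0L, ], 2, mu0)^2)),
                   sqrt(rowSums(sweep(z[l == 1L, ], 2, mu1)^2))))
  between <- sqrt(sum((mu0 - mu1)^2))
  expect_gt(between, within)
})

test_that("training without both classes is rejected with fallback guidance", {
  ps <- fx_toy_patches()
  ps$weak_labels[] <- 0L
  expect_error(train_dcaetl(ps, dcae_config(epochs = 1)), "train_dcae")
})

test_that("the reconstruction-only DCAE trains and embeds on the same contract", {
  cfg <- dcae_config(epochs = 3, batch_size = 64, seed = 3)
  enc <- train_dcae(fx_toy_patches(), cfg)
  expect_lt(tail(enc$loss_history, 1), enc$loss_history[1])
  z <- dcae_embed(enc, fx_toy_patches()$patches)
  expect_lt(max(abs(sqrt(rowSums(z^2)) - 1)), 1e-5)
})

test_that("full autoencoder gradients match finite differences", {
  # joint check through encoder, bottleneck normalization and decoder
  cfg <- dcae_config(latent_dim = 4, encoder_filters = c(3L, 4L), seed = 2)
  mdl <- imatq:::dcae_init(cfg)
  set.seed(11)
  x <- array(rnorm(16 * 16 * 2 * 2), c(16, 16, 2, 2))   # internal [H,W,N,C]
  loss_of <- function(params) {
    fw <- imatq:::dcae_forward(params, mdl$bn, x, TRUE)
    imatq:::mse_loss_i(x, fw$xhat) + sum(fw$z * seq_len(length(fw$z)) * 1e-2)
  }
  fw <- imatq:::dcae_forward(mdl$params, mdl$bn, x, TRUE)
  dz <- matrix(seq_len(length(fw$z)) * 1e-2, nrow(fw$z))
  grads <- imatq:::dcae_backward(mdl$params, fw, imatq:::mse_grad_i(x, fw$xhat), dz)
  for (nm in c("c1_W", "bn1_g", "c2_W", "de_W", "dd_W", "t1_W", "t2_W")) {
    p0 <- mdl$params[[nm]]
    num <- array(0, dim = dim(p0) %||% length(p0))
    idx <- seq_len(min(6L, length(p0)))
    for (i in idx) {
      pp <- mdl$params; pp[[nm]][i] <- pp[[nm]][i] + 1e-5
      pm <- mdl$params; pm[[nm]][i] <- pm[[nm]][i] - 1e-5
      num[i] <- (loss_of(pp) - loss_of(pm)) / 2e-5
    }
    expect_lt(max(abs(grads[[nm]][idx] - num[idx])) /
                max(1e-6, max(abs(grads[[nm]][idx]))), 1e-3,
              label = sprintf("gradient of %s", nm))
  }
})
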