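# Embedding clustering, pixel classification, baselines, DEC machinery.

test_that("k-means on a separating embedding labels both clusters correctly", {
  enc <- fx_toy_encoder()
  ps <- fx_toy_patches()
  cm <- fit_clusters(enc, ps, seed = 2)
  expect_equal(sort(cm$cluster_to_label), c(0L, 1L))
  expect_equal(nrow(cm$centroids), 2L)
  # training-set assignment accuracy is perfect on the separable toy set
  z <- dcae_embed(enc, ps$patches)
  d1 <- rowSums(sweep(z, 2, cm$centroids[1, ])^2)
  d2 <- rowSums(sweep(z, 2, cm$centroids[2, ])^2)
  pred <- cm$cluster_to_label[ifelse(d1 <= d2, 1L, 2L)]
  expect_equal(mean(pred == ps$weak_labels), 1)
  cm2 <- fit_clusters(enc, ps, seed = 2)
  expect_identical(cm$centroids, cm2$centroids)
})

test_that("boundary pixels inherit the nearest interior label", {
  mask <- matrix(FALSE, 40, 40); mask[5:36, 5:36] <- TRUE
  er <- imatq:::erode_patch_window(mask)
  labels <- matrix(0L, 40, 40)
  labels[er] <- 1L   # all-viable interior
  out <- imatq:::fill_boundary_labels(labels, mask, er)
  expect_true(all(out$labels[mask] == 1L))
  expect_true(all(out$labels[!mask] == 0L))
  # split interior: left half viable, right half IMAT; fill follows geometry
  labels2 <- matrix(0L, 40, 40)
  labels2[er] <- ifelse(which(er, arr.ind = TRUE)[, 2] <= 20, 1L, 2L)
  out2 <- imatq:::fill_boundary_labels(labels2, mask, er)
  expect_equal(out2$labels[20, 5], 1L)    # left boundary -> viable
  expect_equal(out2$labels[20, 36], 2L)   # right boundary -> IMAT
  expect_true(all(out2$labels[mask] %in% c(1L, 2L)))
})

test_that("intensity k-means separates bimodal maps and reports degeneracy", {
  set.seed(1)
  mask <- matrix(TRUE, 30, 30)
  t2 <- matrix(40, 30, 30); t2[, 16:30] <- 150
  pd <- matrix(1, 30, 30) + matrix(rnorm(900, 0, 0.01), 30)
  out <- baseline_intensity_kmeans(t2, pd, mask, seed = 3)
  truth <- matrix(1L, 30, 30); truth[, 16:30] <- 2L
  expect_equal(mean(out$labels == truth), 1)  # higher T2 -> IMAT
  expect_error(baseline_intensity_kmeans(matrix(1, 8, 8), matrix(1, 8, 8),
                                         matrix(TRUE, 8, 8), seed = 1),
               "degenerate")
  expect_error(baseline_intensity_kmeans(t2, pd, matrix(FALSE, 30, 30), seed = 1),
               "2 pixels")
  out2 <- baseline_intensity_kmeans(t2, pd, mask, seed = 3)
  expect_identical(out$labels, out2$labels)
})

test_that("Student's-t soft assignment matches hand arithmetic and normalizes", {
  mu <- rbind(c(0, 0), c(2, 0))
  expect_equal(drop(soft_assignment(c(1, 0), mu)), c(0.5, 0.5))
  # z at the first centroid with squared distance 3 to the second (Eq. values)
  mu2 <- rbind(c(0, 0), c(sqrt(3), 0))
  expect_equal(drop(soft_assignment(c(0, 0), mu2)), c(0.8, 0.2))
  set.seed(2)
  Q <- soft_assignment(matrix(rnorm(40), 20), rbind(rnorm(2), rnorm(2)))
  expect_lt(max(abs(rowSums(Q) - 1)), 1e-12)
})

test_that("target distribution sharpens assignments and preserves symmetry", {
  Qu <- matrix(0.5, 4, 2)
  expect_equal(target_distribution(Qu), Qu)
  expect_equal(drop(target_distribution(rbind(c(0.9, 0.1)))), c(0.9, 0.1))
  Q <- rbind(c(0.6, 0.4), c(0.4, 0.6))
  P <- target_distribution(Q)
  expect_gt(P[1, 1], Q[1, 1])
  expect_gt(P[2, 2], Q[2, 2])
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_error(target_distribution(matrix(numeric(0), 0, 2)), "non-empty")
})

test_that("KL divergence vanishes iff the distributions agree", {
  P <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  expect_equal(imatq:::kl_divergence(P, P), 0)
  expect_gt(imatq:::kl_divergence(P, rbind(c(0.5, 0.5), c(0.5, 0.5))), 0)
})

test_that("deep embedded clustering fine-tunes and stops on stable assignments", {
  cfg <- dcae_config(epochs = 4, batch_size = 64, seed = 7)
  cm <- train_dcae_dc(fx_toy_patches(), cfg, update_interval = 2L,
                      pretrain_epochs = 3L)
  expect_s3_class(cm, "cluster_model")
  expect_equal(sort(cm$cluster_to_label), c(0L, 1L))
  # separable toy data stabilizes hard assignments quickly
  expect_true(cm$stopped_early || cm$iterations <= 4 * 2)
})
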