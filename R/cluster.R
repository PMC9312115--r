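# k-means tissue clustering in the learned embedding space, the intensity
# baseline, and deep embedded clustering (DEC-style fine-tuning).

#' Fit the two-cluster tissue model in embedding space
#'
#' Embeds all patches with the trained encoder, runs k-means with k = 2
#' (k-means++-style multiple restarts via `nstart`), and assigns each cluster
#' the majority weak label of its members.
#'
#' @param encoder A trained `dcae_model`.
#' @param patchset Patch set with weak labels.
#' @param seed Integer seed for k-means restarts.
#' @param nstart k-means restarts (default 10).
#' @return An object of class `cluster_model`: `centroids` (2 x latent),
#'   `cluster_to_label` (integer vector mapping cluster 1/2 to 1 = viable /
#'   0 = IMAT), and the `encoder`.
#' @export
fit_clusters <- function(encoder, patchset, seed = 1L, nstart = 10L) {
  stopifnot(inherits(encoder, "dcae_model"))
  z <- dcae_embed(encoder, patchset$patches)
  km <- with_seed(seed, stats::kmeans(z, centers = 2L, nstart = nstart))
  lab <- patchset$weak_labels
  map <- integer(2L)
  for (k in 1:2) {
    members <- lab[km$cluster == k]
    members <- members[!is.na(members)]
    if (!length(members)) stop("cluster without labeled members", call. = FALSE)
    map[k] <- as.integer(round(mean(members) > 0.5))
  }
  if (map[1] == map[2]) {
    stop(paste("degenerate separation: both clusters majority-map to the same",
               "tissue label; the embedding does not separate the classes"),
         call. = FALSE)
  }
  structure(list(centroids = km$centers, cluster_to_label = map,
                 encoder = encoder, method = "kmeans"),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model (%s): 2 centroids in %d-d latent space; cluster->label %s\n",
              x$method, ncol(x$centroids),
              paste(ifelse(x$cluster_to_label == 1L, "viable", "IMAT"), collapse = "/")))
  invisible(x)
}

#' Classify muscle pixels into viable muscle and IMAT
#'
#' Interior pixels (surviving the 16x16 erosion) are labeled by
#' nearest-centroid assignment of their patch embedding; boundary pixels
#' (inside the muscle mask but removed by the erosion) take the label of the
#' nearest interior pixel by Euclidean distance, so every muscle pixel
#' receives exactly one tissue label.
#'
#' @param model A [fit_clusters()] result.
#' @param t2,pd Maps the patches are cropped from.
#' @param muscle_mask Logical muscle-region image.
#' @param encoder Encoder to embed with; defaults to the model's.
#' @return A [tissue_label_map()].
#' @export
classify_pixels <- function(model, t2, pd, muscle_mask, encoder = model$encoder) {
  stopifnot(inherits(model, "cluster_model"))
  ps <- extract_patches(t2, pd, muscle_mask)
  z <- dcae_embed(encoder, ps$patches)
  d1 <- rowSums(sweep(z, 2L, model$centroids[1L, ])^2)
  d2 <- rowSums(sweep(z, 2L, model$centroids[2L, ])^2)
  cl <- ifelse(d1 <= d2, 1L, 2L)
  lab01 <- model$cluster_to_label[cl]   # 1 viable / 0 IMAT
  labels <- matrix(LABEL_BACKGROUND, nrow(muscle_mask), ncol(muscle_mask))
  labels[ps$centers] <- ifelse(lab01 == 1L, LABEL_VIABLE, LABEL_IMAT)
  fill_boundary_labels(labels, muscle_mask, ps$eroded_mask)
}

# propagate interior labels to mask pixels removed by erosion: each boundary
# pixel takes the label of its nearest interior pixel (Euclidean distance)
fill_boundary_labels <- function(labels, muscle_mask, interior_mask) {
  boundary <- muscle_mask & !interior_mask
  if (any(boundary)) {
    bi <- which(boundary, arr.ind = TRUE)
    ii <- which(interior_mask, arr.ind = TRUE)
    ilab <- labels[ii]
    # chunked nearest-neighbor search keeps the distance matrix small
    chunk <- 512L
    for (s in seq(1L, nrow(bi), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(bi))
      dr <- outer(bi[s:e, 1L], ii[, 1L], "-")
      dc <- outer(bi[s:e, 2L], ii[, 2L], "-")
      nn <- max.col(-(dr^2 + dc^2), ties.method = "first")
      labels[bi[s:e, , drop = FALSE]] <- ilab[nn]
    }
  }
  tissue_label_map(labels, muscle_mask)
}

#' Intensity-based k-means baseline
#'
#' Applies plain k-means with k = 2 to the per-pixel (T2, PD) intensity
#' vectors inside the muscle mask. Clusters are mapped to tissue labels by
#' the majority weak label when a label map is supplied, otherwise by mean
#' T2 ordering (the higher-T2 cluster is IMAT, fat having the longer T2).
#'
#' @param t2,pd Intensity maps.
#' @param muscle_mask Logical muscle-region image.
#' @param seed Integer seed.
#' @param weak_label_map Optional [tissue_label_map()] for majority mapping.
#' @param nstart k-means restarts (default 10).
#' @return A [tissue_label_map()].
#' @export
baseline_intensity_kmeans <- function(t2, pd, muscle_mask, seed = 1L,
                                      weak_label_map = NULL, nstart = 10L) {
  sel <- which(muscle_mask)
  if (length(sel) < 2L) stop("muscle mask must contain at least 2 pixels", call. = FALSE)
  X <- cbind(t2[sel], pd[sel])
  if (all(apply(X, 2L, stats::sd) < .Machine$double.eps)) {
    stop("degenerate clustering: identical intensities at every masked pixel",
         call. = FALSE)
  }
  km <- with_seed(seed, stats::kmeans(X, centers = 2L, nstart = nstart))
  map <- integer(2L)
  if (!is.null(weak_label_map)) {
    wl <- weak_label_map$labels[sel]
    for (k in 1:2) {
      members <- wl[km$cluster == k & wl != LABEL_BACKGROUND]
      map[k] <- if (mean(members == LABEL_VIABLE) > 0.5) 1L else 0L
    }
    if (map[1] == map[2]) {
      # fall back to T2 ordering when the vote degenerates
      map <- if (km$centers[1L, 1L] < km$centers[2L, 1L]) c(1L, 0L) else c(0L, 1L)
    }
  } else {
    map <- if (km$centers[1L, 1L] < km$centers[2L, 1L]) c(1L, 0L) else c(0L, 1L)
  }
  labels <- matrix(LABEL_BACKGROUND, nrow(muscle_mask), ncol(muscle_mask))
  labels[sel] <- ifelse(map[km$cluster] == 1L, LABEL_VIABLE, LABEL_IMAT)
  tissue_label_map(labels, muscle_mask)
}

#' Train the DCAE + k-means baseline
#'
#' Trains the auto-encoder with reconstruction loss only, then clusters the
#' embedding with k-means and majority-labels the clusters.
#'
#' @inheritParams train_dcaetl
#' @param seed Seed for the k-means stage (the DCAE uses `config$seed`).
#' @return A `cluster_model` (method `"dcae_kmeans"`).
#' @export
train_dcae_kmeans <- function(patchset, config = dcae_config(), seed = 1L,
                              verbose = FALSE) {
  enc <- train_dcae(patchset, config, verbose = verbose)
  cm <- fit_clusters(enc, patchset, seed = seed)
  cm$method <- "dcae_kmeans"
  cm
}

#' Student's-t soft cluster assignment
#'
#' `q_j` is proportional to `(1 + ||z - mu_j||^2)^-1`, normalized over
#' clusters (one degree of freedom).
#'
#' @param z Latent vector, or a matrix with one row per point.
#' @param centroids Matrix of cluster centers (rows).
#' @return Matrix of soft assignments; rows sum to 1.
#' @export
soft_assignment <- function(z, centroids) {
  if (is.null(dim(z))) z <- rbind(z)
  s <- vapply(seq_len(nrow(centroids)), function(j) {
    1 / (1 + rowSums(sweep(z, 2L, centroids[j, ])^2))
  }, numeric(nrow(z)))
  if (is.null(dim(s))) s <- rbind(s)
  s / rowSums(s)
}

#' Target distribution for deep embedded clustering
#'
#' `p_ij = (q_ij^2 / f_j) / sum_j (q_ij^2 / f_j)` with cluster frequencies
#' `f_j = sum_i q_ij`; sharpens the soft assignments while normalizing by
#' cluster size.
#'
#' @param Q Soft-assignment matrix (rows sum to 1).
#' @return Matrix of the same shape; rows sum to 1.
#' @export
target_distribution <- function(Q) {
  if (is.null(dim(Q))) Q <- rbind(Q)
  if (nrow(Q) == 0L) stop("`Q` must be non-empty", call. = FALSE)
  f <- colSums(Q)
  W <- sweep(Q^2, 2L, f, "/")
  W / rowSums(W)
}

# KL(P || Q), summed over points
kl_divergence <- function(P, Q) {
  sel <- P > 0
  sum(P[sel] * (log(P[sel]) - log(pmax(Q[sel], 1e-12))))
}

#' Train the deep-embedded-clustering comparison method (DCAE_DC)
#'
#' Pretrains the DCAE with reconstruction loss (1 epoch by default),
#' initializes two trainable cluster centers by k-means on the embeddings,
#' then fine-tunes network and centers under `L = L_r + gamma * KL(P || Q)`
#' with Student's-t soft assignments. The target distribution P is recomputed
#' from all embedded points every `update_interval` iterations; training
#' stops when the fraction of points whose hard assignment changed between
#' consecutive P-updates falls below `stop_delta` (or at the epoch cap).
#'
#' @param patchset Patch set (weak labels used only for final cluster
#'   labeling).
#' @param config A [dcae_config()]; `config$epochs` caps fine-tuning.
#' @param gamma Clustering-loss weight (default 0.1).
#' @param update_interval Iterations between P-updates (default 200).
#' @param stop_delta Assignment-change stopping threshold (default 1e-4).
#' @param pretrain_epochs Reconstruction-only pretraining epochs (default 1;
#'   configurable because one epoch is a deliberately light initialization).
#' @param verbose Print progress.
#' @return A `cluster_model` (method `"dcae_dc"`).
#' @export
train_dcae_dc <- function(patchset, config = dcae_config(), gamma = 0.1,
                          update_interval = 200L, stop_delta = 1e-4,
                          pretrain_epochs = 1L, verbose = FALSE) {
  pre_cfg <- config
  pre_cfg$epochs <- as.integer(pretrain_epochs)
  enc <- train_dcae(patchset, pre_cfg, verbose = verbose)
  params <- enc$params; bn <- enc$bn
  z <- dcae_embed(enc, patchset$patches)
  km <- with_seed(child_seed(config$seed, 17L), stats::kmeans(z, 2L, nstart = 10L))
  mu <- km$centers
  hard_prev <- km$cluster
  P_all <- target_distribution(soft_assignment(z, mu))
  state <- adam_init(c(params, list(mu = mu)))
  m <- dim(patchset$patches)[4]
  bs <- min(config$batch_size, m)
  it <- 0L
  stopped <- FALSE
  with_seed(child_seed(config$seed, 19L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(m)
      for (s in seq(1L, m, by = bs)) {
        sel <- ord[s:min(s + bs - 1L, m)]
        xb <- nc_in(patchset$patches[, , , sel, drop = FALSE])
        fw <- dcae_forward(params, bn, xb, TRUE); bn <- fw$bn
        zb <- fw$z
        sj <- vapply(1:2, function(j) 1 / (1 + rowSums(sweep(zb, 2L, mu[j, ])^2)),
                     numeric(length(sel)))
        qb <- sj / rowSums(sj)
        pb <- P_all[sel, , drop = FALSE]
        # dKL/dz_i = 2 sum_j s_ij (q_ij - p_ij) (z_i - mu_j); mirrored for mu
        dz <- matrix(0, length(sel), ncol(zb))
        dmu <- matrix(0, 2L, ncol(zb))
        for (j in 1:2) {
          wj <- sj[, j] * (qb[, j] - pb[, j])
          diffj <- sweep(zb, 2L, mu[j, ])
          dz <- dz + 2 * wj * diffj
          dmu[j, ] <- -2 * colSums(wj * diffj)
        }
        grads <- dcae_backward(params, fw, mse_grad_i(xb, fw$xhat), gamma * dz)
        grads$mu <- gamma * dmu
        upd <- adam_step(c(params, list(mu = mu)), grads, state, lr = config$lr)
        state <- upd$state
        mu <- upd$params$mu
        params <- upd$params[setdiff(names(upd$params), "mu")]
        if (any(!is.finite(unlist(grads$mu))) || any(!is.finite(mu))) {
          stop("divergent clustering loss (non-finite centers)", call. = FALSE)
        }
        it <- it + 1L
        if (it %% update_interval == 0L) {
          enc$params <- params; enc$bn <- bn
          z <- dcae_embed(enc, patchset$patches)
          Q_all <- soft_assignment(z, mu)
          P_all <- target_distribution(Q_all)
          hard <- max.col(Q_all, ties.method = "first")
          changed <- mean(hard != hard_prev)
          hard_prev <- hard
          if (verbose) message(sprintf("iter %d: %.4f assignments changed", it, changed))
          if (changed < stop_delta) { stopped <- TRUE; break }
        }
      }
      if (stopped) break
    }
  })
  enc$params <- params; enc$bn <- bn
  z <- dcae_embed(enc, patchset$patches)
  Q_all <- soft_assignment(z, mu)
  cl <- max.col(Q_all, ties.method = "first")
  lab <- patchset$weak_labels
  map <- integer(2L)
  for (k in 1:2) {
    members <- lab[cl == k]
    members <- members[!is.na(members)]
    if (!length(members)) stop("cluster without labeled members", call. = FALSE)
    map[k] <- as.integer(round(mean(members) > 0.5))
  }
  if (map[1] == map[2]) {
    stop("degenerate separation: both clusters majority-map to the same tissue label",
         call. = FALSE)
  }
  structure(list(centroids = mu, cluster_to_label = map, encoder = enc,
                 method = "dcae_dc", iterations = it, stopped_early = stopped),
            class = "cluster_model")
}
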