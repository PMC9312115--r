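# Shared, lazily built test fixtures. Everything is generated in code at
# test time; the dictionary and fitted slices are memoized in this
# environment (and the dictionary additionally in the on-disk session cache)
# so the cost is paid once per test run.

.fixtures <- new.env(parent = emptyenv())

fx_protocol <- function() mese_protocol()

fx_dictionary <- function() {
  if (is.null(.fixtures$dict)) .fixtures$dict <- build_dictionary(fx_protocol())
  .fixtures$dict
}

# one prepared slice: phantom + noiseless/noisy series + fitted maps
fx_slice <- function(target = 0.3, seed = 11L, shape = 128L, snr = 50,
                     two_component = TRUE) {
  key <- paste0("slice_", target, "_", seed, "_", shape, "_",
                if (is.null(snr)) "none" else snr, "_", two_component)
  if (is.null(.fixtures[[key]])) {
    p <- fx_protocol(); d <- fx_dictionary()
    ph <- make_phantom(shape, "calf", target, seed = seed)
    s <- simulate_mese(ph, p, d, snr = snr, seed = seed)
    musc <- ph$muscle_region_mask
    maps <- if (two_component) fit_two_component(s, d, mask = musc)
            else fit_t2_pd(s, d, mask = musc)
    t2 <- maps$t2; t2[is.na(t2)] <- 0
    pd <- maps$pd; pd[is.na(pd)] <- 0
    .fixtures[[key]] <- list(
      truth = ph, series = s, maps = maps, musc = musc,
      t2n = normalize_input(t2)$map, pdn = normalize_input(pd)$map,
      truth_labels = truth_label_map(ph),
      gt_labels = if (two_component) label_tissue_gt(maps$fat_fraction, musc) else NULL)
  }
  .fixtures[[key]]
}

# small two-class synthetic patch set with clearly separated appearance,
# for exercising the DCAE machinery without a full phantom
fx_toy_patches <- function(m_per_class = 60L, seed = 4L) {
  key <- paste0("toy_", m_per_class, "_", seed)
  if (is.null(.fixtures[[key]])) {
    set.seed(seed)
    m <- 2L * m_per_class
    patches <- array(0, dim = c(16, 16, 2, m))
    labels <- integer(m)
    for (i in seq_len(m)) {
      cls <- (i - 1L) %/% m_per_class   # 0 = IMAT-like, 1 = viable-like
      mu <- if (cls == 0L) c(2, 1) else c(-0.5, -0.2)
      patches[, , 1, i] <- matrix(rnorm(256, mu[1], 0.3), 16, 16)
      patches[, , 2, i] <- matrix(rnorm(256, mu[2], 0.3), 16, 16)
      labels[i] <- 1L - cls  # viable coded 1
    }
    .fixtures[[key]] <- structure(
      list(patches = patches, centers = cbind(rep(8L, m), rep(8L, m)),
           weak_labels = labels, source_slice = rep(1L, m)),
      class = "patch_set")
  }
  .fixtures[[key]]
}

# tiny trained DCAETL on the toy patches, reused by clustering tests
fx_toy_encoder <- function() {
  if (is.null(.fixtures$toy_enc)) {
    cfg <- dcae_config(epochs = 4L, batch_size = 64L, seed = 7L)
    .fixtures$toy_enc <- train_dcaetl(fx_toy_patches(), cfg)
  }
  .fixtures$toy_enc
}

# deterministic subsample of a patch set
subsample_patchset <- function(ps, n_keep, seed = 99L) {
  m <- dim(ps$patches)[4]
  if (m <= n_keep) return(ps)
  keep <- imatq:::with_seed(seed, sort(sample.int(m, n_keep)))
  ps$patches <- ps$patches[, , , keep, drop = FALSE]
  ps$centers <- ps$centers[keep, , drop = FALSE]
  ps$weak_labels <- ps$weak_labels[keep]
  ps$source_slice <- ps$source_slice[keep]
  ps
}

`%||%` <- function(a, b) if (is.null(a)) b else a
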