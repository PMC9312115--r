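# Bias-field correction, anatomy cropping, input normalization.

# flat-foreground synthetic series multiplied by a known smooth field
make_biased_series <- function(seed = 1, n = 96) {
  set.seed(seed)
  p <- mese_protocol(n_echoes = 5)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE); rr <- matrix(seq_len(n), n, n)
  u <- (cc - (n + 1) / 2) / (n / 2); v <- (rr - (n + 1) / 2) / (n / 2)
  fg <- (u / 0.8)^2 + (v / 0.7)^2 <= 1
  base <- matrix(0, n, n)
  base[fg] <- 1 * rnorm(sum(fg), 1, 0.04)
  field <- 1 + 0.18 * (u + 0.6 * v - 0.5 * u * v + 0.3 * (u^2 - 0.5))
  arr <- array(0, dim = c(n, n, 5))
  for (k in 1:5) arr[, , k] <- base * exp(-k / 3) * field
  list(series = echo_series(arr, p), clean = base, field = field, fg = fg)
}

test_that("a known smooth multiplicative field is removed within 3%", {
  bs <- make_biased_series()
  out <- correct_receiver_bias(bs$series)
  ratio <- out$series$data[, , 1][bs$fg] / (bs$clean * exp(-1 / 3))[bs$fg]
  expect_lt(max(abs(ratio - 1)), 0.03)
  # estimated field reproduces the injected one up to its foreground mean
  f_true <- bs$field / mean(bs$field[out$foreground])
  expect_lt(max(abs(out$bias_field_estimate[bs$fg] / f_true[bs$fg] - 1)), 0.03)
})

test_that("a spatially flat profile passes through unchanged", {
  p <- mese_protocol(n_echoes = 3)
  n <- 64
  cc <- matrix(seq_len(n), n, n, byrow = TRUE); rr <- matrix(seq_len(n), n, n)
  fg <- (cc - 32)^2 + (rr - 32)^2 <= 25^2
  arr <- array(0, dim = c(n, n, 3))
  for (k in 1:3) arr[, , k] <- fg * (4 - k)
  out <- correct_receiver_bias(echo_series(arr, p))
  e1 <- out$series$data[, , 1]
  expect_lt(max(abs(e1[fg] / arr[, , 1][fg] - 1)), 1e-6)
  expect_lt(abs(mean(out$bias_field_estimate[out$foreground]) - 1), 1e-6)
})

test_that("correction is idempotent within 1% on phantom data", {
  sl <- fx_slice(0.3, seed = 11, two_component = FALSE)
  once <- correct_receiver_bias(sl$series)
  twice <- correct_receiver_bias(once$series)
  fg <- once$foreground
  rel <- abs(twice$series$data[, , 1][fg] - once$series$data[, , 1][fg]) /
    pmax(once$series$data[, , 1][fg], 1e-9)
  expect_lt(stats::quantile(rel, 0.99, names = FALSE), 0.01)
})

test_that("all-zero input is rejected", {
  p <- mese_protocol(n_echoes = 3)
  expect_error(correct_receiver_bias(echo_series(array(0, c(16, 16, 3)), p)),
               "all-zero")
})

test_that("cropping finds the anatomy bounding box and resizes to target", {
  ph <- make_phantom(128, "calf", 0.2, seed = 4)
  sl <- fx_slice(0.2, seed = 4, shape = 128, two_component = FALSE)
  first <- sl$series$data[, , 1]
  out <- crop_and_resize(sl$series$data, masks = list(muscle = ph$muscle_region_mask),
                         out_size = 128)
  expect_equal(dim(out$stack), c(128, 128, 17))
  expect_true(is.logical(out$masks$muscle))
  # analytic outer-ellipse extents from the phantom geometry
  ctr <- ph$geometry$center
  ax <- ph$geometry$semi_axes_px
  expect_lte(abs(out$crop_bbox[["r0"]] - (ctr - ax[2] - 2)), 3 + 2)
  expect_lte(abs(out$crop_bbox[["r1"]] - (ctr + ax[2] + 2)), 3 + 2)
  expect_lte(abs(out$crop_bbox[["c0"]] - (ctr - ax[1] - 2)), 3 + 2)
  expect_lte(abs(out$crop_bbox[["c1"]] - (ctr + ax[1] + 2)), 3 + 2)
  # deterministic
  out2 <- crop_and_resize(sl$series$data, out_size = 128)
  expect_identical(out$crop_bbox, out2$crop_bbox)
})

test_that("an empty image yields an explicit error", {
  expect_error(crop_and_resize(matrix(0, 64, 64)), "foreground|empty")
})

test_that("normalization clips at the percentile and z-scores exactly", {
  set.seed(8)
  img <- matrix(rexp(64 * 64), 64, 64)
  out <- normalize_input(img)
  expect_lt(abs(mean(out$map)), 1e-6)
  expect_lt(abs(stats::sd(as.vector(out$map)) - 1), 1e-6)
  expect_equal(out$clip_value, stats::quantile(img, 0.98, names = FALSE))
  # a single extreme outlier is clipped to the 98th percentile
  img[1, 1] <- 1e6
  out2 <- normalize_input(img)
  expect_lt(out2$clip_value, 1e6)
  expect_equal(max(out2$map), out2$map[1, 1])
  expect_error(normalize_input(matrix(3, 8, 8)), "variance")
})
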