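# Phantom generation: geometry, label consistency, determinism, simulation.

test_that("achieved IMAT fraction tracks the request", {
  ph <- make_phantom(128, "calf", 0.25, seed = 7)
  expect_lte(abs(ph$imat_fraction_true - 0.25), 0.02)
  # recompute from the mask itself
  frac <- sum(ph$tissue_mask == 3) / sum(ph$tissue_mask %in% c(2, 3))
  expect_equal(frac, ph$imat_fraction_true)
})

test_that("zero target yields no IMAT pixels", {
  ph <- make_phantom(64, "calf", 0, seed = 3)
  expect_equal(sum(ph$tissue_mask == 3), 0L)
  expect_equal(ph$imat_fraction_true, 0)
})

test_that("identical arguments and seed reproduce the phantom bit-for-bit", {
  expect_identical(make_phantom(64, "thigh", 0.4, seed = 12),
                   make_phantom(64, "thigh", 0.4, seed = 12))
})

test_that("mask invariants hold across random phantoms", {
  for (i in 1:50) {
    target <- ((i * 7) %% 90) / 100
    ph <- make_phantom(64, if (i %% 2) "calf" else "thigh", target, seed = 1000 + i)
    expect_lte(abs(ph$imat_fraction_true - target), 0.02)
    # muscle mask is exactly the union of viable and IMAT codes
    expect_identical(ph$muscle_region_mask, ph$tissue_mask %in% c(2, 3) &
                       matrix(TRUE, 64, 64))
    # fat-fraction threshold consistency inside the muscle region
    musc <- ph$muscle_region_mask
    expect_identical(unname(ph$fat_fraction[musc] > 0.5),
                     unname(ph$tissue_mask[musc] == 3))
  }
})

test_that("muscle region is one connected component inside the SAT ring", {
  for (seed in c(5, 6)) {
    ph <- make_phantom(96, "calf", 0.3, seed = seed)
    lab <- EBImage::bwlabel(EBImage::Image(ph$muscle_region_mask * 1))
    expect_equal(max(lab), 1)
    # strictly inside the SAT: dilating muscle by one pixel stays within the leg
    expect_true(all(ph$tissue_mask[ph$muscle_region_mask] %in% c(2, 3)))
  }
})

test_that("out-of-range requests are rejected", {
  expect_error(make_phantom(32, "calf", 0.2), "64")
  expect_error(make_phantom(128, "calf", 0.97), "0.95")
})

test_that("noiseless simulation matches the closed form on ideal pixels", {
  p <- fx_protocol(); d <- fx_dictionary()
  ph <- make_phantom(64, "calf", 0, seed = 2)
  # force an analytically known pixel population
  ph$fat_fraction[] <- 0
  ph$b1_plus[] <- 1
  ph$b1_minus[] <- 1
  ph$t2_water[] <- 50
  s <- simulate_mese(ph, p, d, snr = NULL)
  px <- which(ph$muscle_region_mask, arr.ind = TRUE)[1, ]
  sig <- s$data[px[1], px[2], ]
  expected <- ph$pd[px[1], px[2]] * exp(-echo_times(p) / 50)
  expect_lt(max(abs(sig - expected) / expected), 1e-6)
  # zero proton density background stays exactly zero
  bg <- which(ph$tissue_mask == 0, arr.ind = TRUE)[1, ]
  expect_identical(unname(s$data[bg[1], bg[2], ]), rep(0, p$n_echoes))
})

test_that("magnitude noise level matches the requested SNR", {
  p <- fx_protocol(); d <- fx_dictionary()
  ph <- make_phantom(128, "calf", 0.2, seed = 9)
  s <- simulate_mese(ph, p, d, snr = 50, seed = 21)
  s2 <- simulate_mese(ph, p, d, snr = 50, seed = 21)
  expect_identical(s$data, s2$data)
  bg <- ph$tissue_mask == 0
  expect_gt(sum(bg), 1000)
  # background magnitudes are Rayleigh; sigma-hat = sqrt(mean(m^2)/2)
  sigma_hat <- sqrt(mean(s$data[bg][1:5000]^2) / 2)
  expect_lt(abs(sigma_hat - s$sigma) / s$sigma, 0.10)
})

test_that("protocol mismatch with the dictionary is rejected", {
  d <- fx_dictionary()
  ph <- make_phantom(64, "calf", 0.2, seed = 1)
  p_other <- mese_protocol(echo_spacing = 10)
  expect_error(simulate_mese(ph, p_other, d), "match")
})

test_that("cohort subjects fall in their severity bands with a stable manifest", {
  p <- fx_protocol(); d <- fx_dictionary()
  co <- make_cohort(6, c(mild = 2, moderate = 2, severe = 2), seed = 1,
                    shape = 64, protocol = p, dictionary = d, snr = NULL)
  expect_equal(nrow(co$manifest), 6L)
  expect_identical(co$manifest$severity,
                   unname(severity_class(co$manifest$imat_fraction_true)))
  co2 <- make_cohort(6, c(mild = 2, moderate = 2, severe = 2), seed = 1,
                     shape = 64, protocol = p, dictionary = d, snr = NULL)
  expect_identical(co$manifest, co2$manifest)
  # single-subject mild cohort stays in [0, 0.33]
  co1 <- make_cohort(1, c(mild = 1), seed = 3, shape = 64, protocol = p,
                     dictionary = d, snr = NULL)
  expect_lte(co1$manifest$imat_fraction_true, 0.33)
})

test_that("cohort files are written when an output directory is given", {
  p <- fx_protocol(); d <- fx_dictionary()
  od <- file.path(tempdir(), "imatq-cohort-test")
  unlink(od, recursive = TRUE)
  co <- make_cohort(2, c(mild = 2), out_dir = od, seed = 5, shape = 64,
                    protocol = p, dictionary = d, snr = 40)
  expect_true(file.exists(file.path(od, "manifest.csv")))
  expect_true(all(file.exists(file.path(od, paste0(co$manifest$subject_id,
                                                   "_echo.nii.gz")))))
  back <- read_echo_series(file.path(od, paste0(co$manifest$subject_id[1],
                                                "_echo.nii.gz")), p)
  expect_equal(back$data, co$subjects[[1]]$series$data, tolerance = 1e-6)
})
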