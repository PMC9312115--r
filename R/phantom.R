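# Synthetic lower-limb phantom with known tissue ground truth.
#
# The phantom emulates an axial calf/thigh cross-section: an outer leg
# ellipse, a subcutaneous fat (SAT) ring bounded inside by the fascia lata, a
# muscle compartment containing speckled IMAT infiltration, and one (thigh) or
# two (calf) cortical bone discs with marrow cores. Per-pixel tissue
# parameters (water/fat T2, proton density, sub-pixel fat fraction) and smooth
# transmit/receive field inhomogeneities are drawn so that every downstream
# stage of the pipeline can be exercised against exact ground truth.

# tissue codes used by phantom_truth$tissue_mask
TISSUE_CODES <- c(background = 0L, sat = 1L, viable = 2L, imat = 3L,
                  bone = 4L, marrow = 5L)

ellipse_mask <- function(u, v, u0, v0, a, b) {
  ((u - u0) / a)^2 + ((v - v0) / b)^2 <= 1
}

# random low-order 2-D polynomial surface with max |deviation| = amp over `inside`
smooth_field <- function(u, v, inside, amp) {
  co <- stats::rnorm(8)
  f <- co[1] * u + co[2] * v + co[3] * u * v + co[4] * (u^2 - 0.5) +
    co[5] * (v^2 - 0.5) + co[6] * u^3 + co[7] * v^3 + co[8] * u^2 * v
  f <- f - mean(f[inside])
  m <- max(abs(f[inside]))
  if (m < .Machine$double.eps) return(matrix(0, nrow(u), ncol(u)))
  f / m * amp
}

#' Generate a synthetic lower-limb phantom with ground truth
#'
#' Builds one axial slice of calf or thigh anatomy with a controllable IMAT
#' burden. IMAT pixels are placed by thresholding a Gaussian-smoothed random
#' field inside the muscle compartment at the quantile matching
#' `target_imat_fraction`, so the achieved fraction tracks the request to
#' within pixel-counting resolution. Per-pixel fat fractions are drawn as
#' viable ~ U(0, 0.2), IMAT ~ U(0.6, 1), SAT/marrow ~ U(0.9, 1), so the
#' >50% fat-fraction labeling rule reproduces the tissue mask exactly.
#'
#' @param shape Image side length in pixels (square), in `[64, 256]`.
#' @param anatomy `"calf"` (tibia + fibula) or `"thigh"` (single femur).
#' @param target_imat_fraction Requested IMAT share of the muscle region, in
#'   `[0, 0.95]`; the muscle must retain viable pixels.
#' @param seed Integer seed; the phantom is bit-for-bit reproducible given it.
#' @param texture_scale Gaussian smoothing radius (pixels) of the IMAT random
#'   field; controls infiltration speckle size.
#' @return An object of class `phantom_truth`: `tissue_mask` (codes 0
#'   background, 1 SAT, 2 viable muscle, 3 IMAT, 4 bone, 5 marrow),
#'   `muscle_region_mask`, `fat_fraction`, `t2_water`, `t2_fat`, `pd`,
#'   `b1_plus`, `b1_minus`, `imat_fraction_true`, `seed`, plus the analytic
#'   outer-ellipse geometry in `geometry`.
#' @examples
#' ph <- make_phantom(64, "calf", 0.3, seed = 1)
#' ph$imat_fraction_true
#' @export
make_phantom <- function(shape = 128L, anatomy = c("calf", "thigh"),
                         target_imat_fraction = 0.2, seed = 1L,
                         texture_scale = 4) {
  anatomy <- match.arg(anatomy)
  shape <- as.integer(shape)
  if (shape < 64L || shape > 256L) {
    stop("`shape` must lie in [64, 256] pixels to fit the leg geometry", call. = FALSE)
  }
  stopifnot_scalar(target_imat_fraction)
  if (target_imat_fraction < 0 || target_imat_fraction > 0.95) {
    stop("`target_imat_fraction` must lie in [0, 0.95] (the muscle must retain viable pixels)",
         call. = FALSE)
  }
  with_seed(seed, {
    n <- shape
    ctr <- (n + 1) / 2
    cc <- matrix(seq_len(n), n, n, byrow = TRUE)
    rr <- matrix(seq_len(n), n, n)
    u <- (cc - ctr) / (n / 2)
    v <- (rr - ctr) / (n / 2)

    # anthropometric proportions: at 1.5 mm/px and a 128-px matrix the leg is
    # ~17 cm wide; the SAT ring is ~1 cm thick (fascia at ~0.85 of the outer
    # contour) and bone diameters are a small fraction of the leg's, so the
    # muscle compartment fills most of the cross-section as in axial
    # thigh/calf MRI
    out_a <- 0.88 + stats::runif(1, -0.03, 0.03)
    out_b <- 0.80 + stats::runif(1, -0.03, 0.03)
    fascia_ratio <- 0.85 + stats::runif(1, -0.02, 0.02)
    leg <- ellipse_mask(u, v, 0, 0, out_a, out_b)
    fascia <- ellipse_mask(u, v, 0, 0, out_a * fascia_ratio, out_b * fascia_ratio)

    if (anatomy == "calf") {
      bones <- list(c(-0.18, 0.06, 0.13), c(0.30, 0.20, 0.07))
    } else {
      bones <- list(c(0.0, -0.05, 0.16))
    }
    bone_mask <- matrix(FALSE, n, n); marrow_mask <- matrix(FALSE, n, n)
    for (b in bones) {
      d <- ellipse_mask(u, v, b[1], b[2], b[3], b[3])
      m <- ellipse_mask(u, v, b[1], b[2], b[3] * 0.55, b[3] * 0.55)
      bone_mask <- bone_mask | (d & !m)
      marrow_mask <- marrow_mask | m
    }

    tissue <- matrix(TISSUE_CODES[["background"]], n, n)
    tissue[leg] <- TISSUE_CODES[["sat"]]
    muscle <- fascia & !bone_mask & !marrow_mask
    tissue[muscle] <- TISSUE_CODES[["viable"]]
    tissue[bone_mask] <- TISSUE_CODES[["bone"]]
    tissue[marrow_mask] <- TISSUE_CODES[["marrow"]]

    # IMAT placement: smoothed random field thresholded at the target quantile
    if (target_imat_fraction > 0) {
      field <- stats::rnorm(n * n)
      dim(field) <- c(n, n)
      field <- as.matrix(EBImage::gblur(EBImage::Image(field), sigma = texture_scale))
      thr <- stats::quantile(field[muscle], 1 - target_imat_fraction, names = FALSE)
      imat <- muscle & (field > thr)
      tissue[imat] <- TISSUE_CODES[["imat"]]
    }

    viable_m <- tissue == TISSUE_CODES[["viable"]]
    imat_m <- tissue == TISSUE_CODES[["imat"]]
    sat_m <- tissue == TISSUE_CODES[["sat"]]
    marrow_m <- tissue == TISSUE_CODES[["marrow"]]
    bone_m <- tissue == TISSUE_CODES[["bone"]]
    muscle_region <- viable_m | imat_m

    ff <- matrix(0, n, n)
    ff[viable_m] <- stats::runif(sum(viable_m), 0, 0.2)
    ff[imat_m] <- stats::runif(sum(imat_m), 0.6, 1.0)
    ff[sat_m] <- stats::runif(sum(sat_m), 0.9, 1.0)
    ff[marrow_m] <- stats::runif(sum(marrow_m), 0.9, 1.0)
    ff[bone_m] <- stats::runif(sum(bone_m), 0, 0.1)

    t2w <- matrix(pmax(stats::rnorm(n * n, 38, 3), 5), n, n)
    t2f <- matrix(pmin(pmax(stats::rnorm(n * n, 150, 10), 100), 250), n, n)
    t2w[bone_m] <- pmax(stats::rnorm(sum(bone_m), 15, 2), 5)

    pd <- matrix(0, n, n)
    pd[viable_m] <- stats::rnorm(sum(viable_m), 1.00, 0.03)
    pd[imat_m] <- stats::rnorm(sum(imat_m), 1.12, 0.03)
    pd[sat_m] <- stats::rnorm(sum(sat_m), 1.15, 0.03)
    pd[marrow_m] <- stats::rnorm(sum(marrow_m), 1.15, 0.03)
    pd[bone_m] <- stats::rnorm(sum(bone_m), 0.18, 0.02)
    pd[pd < 0.01 & leg] <- 0.01

    b1p <- 1 + smooth_field(u, v, leg, stats::runif(1, 0.10, 0.20))
    b1p <- pmin(pmax(b1p, 0.7), 1.3)
    b1m <- 1 + smooth_field(u, v, leg, stats::runif(1, 0.10, 0.20))
    b1m <- pmin(pmax(b1m, 0.5), 1.5)

    structure(list(
      tissue_mask = tissue, muscle_region_mask = muscle_region,
      fat_fraction = ff, t2_water = t2w, t2_fat = t2f, pd = pd,
      b1_plus = b1p, b1_minus = b1m,
      imat_fraction_true = sum(imat_m) / sum(muscle_region),
      seed = as.integer(seed), anatomy = anatomy, shape = n,
      geometry = list(center = ctr, semi_axes_px = c(out_a, out_b) * n / 2,
                      fascia_ratio = fascia_ratio)
    ), class = "phantom_truth")
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %dx%d %s, IMAT fraction %.3f (seed %d)\n",
              x$shape, x$shape, x$anatomy, x$imat_fraction_true, x$seed))
  invisible(x)
}

#' Construct an echo-series object
#'
#' @param data Numeric array `H x W x n_echoes` of magnitude images.
#' @param protocol The [mese_protocol()] the series was acquired under.
#' @param ... Additional metadata fields stored alongside.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(data, protocol, ...) {
  stopifnot(inherits(protocol, "mese_protocol"))
  if (length(dim(data)) != 3L || dim(data)[3] != protocol$n_echoes) {
    stop("`data` must be H x W x n_echoes matching the protocol", call. = FALSE)
  }
  structure(c(list(data = data, protocol = protocol), list(...)),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("echo_series: %d x %d pixels, %d echoes (dTE %.2f ms)\n",
              d[1], d[2], d[3], x$protocol$echo_spacing))
  invisible(x)
}

#' Simulate a MESE acquisition of a phantom
#'
#' Generates the per-pixel echo decay from the two-compartment water/fat
#' model: `signal(TE_k) = b1_minus * pd * ((1 - ff) * curve(t2_water, b1_plus)
#' + ff * curve(t2_fat, b1_plus))`, with decay curves looked up from the
#' dictionary at the nearest (T2, B1+) grid entry. Optional Rician noise is
#' applied as the magnitude of the signal plus complex Gaussian noise with
#' per-channel standard deviation `sigma = mean(first-echo muscle signal)/snr`
#' (the physically standard model for magnitude MRI).
#'
#' @param truth A [make_phantom()] result.
#' @param protocol The acquisition protocol; must match the dictionary's.
#' @param dictionary A [build_dictionary()] result.
#' @param snr Signal-to-noise ratio of the first-echo muscle signal, or
#'   `NULL` for a noiseless acquisition.
#' @param seed Integer seed for the noise draw.
#' @return An [echo_series()] carrying `sigma` (the applied noise level).
#' @export
simulate_mese <- function(truth, protocol, dictionary, snr = NULL, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(dictionary, "mese_dictionary"))
  if (!identical(protocol_signature(protocol), protocol_signature(dictionary$protocol))) {
    stop("`protocol` does not match the dictionary protocol", call. = FALSE)
  }
  n <- truth$shape; ne <- protocol$n_echoes
  iw <- dict_entry_index(dictionary, as.vector(truth$t2_water), as.vector(truth$b1_plus))
  ifa <- dict_entry_index(dictionary, as.vector(truth$t2_fat), as.vector(truth$b1_plus))
  ffv <- as.vector(truth$fat_fraction)
  amp <- as.vector(truth$b1_minus) * as.vector(truth$pd)
  sig <- (1 - ffv) * dictionary$raw_curves[iw, , drop = FALSE] +
    ffv * dictionary$raw_curves[ifa, , drop = FALSE]
  sig <- sig * amp
  sigma <- NA_real_
  if (!is.null(snr)) {
    stopifnot_scalar(snr)
    if (snr <= 0) stop("`snr` must be positive", call. = FALSE)
    sigma <- mean(sig[as.vector(truth$muscle_region_mask), 1L]) / snr
    sig <- with_seed(seed, {
      n1 <- matrix(stats::rnorm(length(sig), sd = sigma), nrow(sig), ne)
      n2 <- matrix(stats::rnorm(length(sig), sd = sigma), nrow(sig), ne)
      sqrt((sig + n1)^2 + n2^2)
    })
  }
  echo_series(array(sig, dim = c(n, n, ne)), protocol,
              snr = if (is.null(snr)) NA_real_ else snr,
              sigma = sigma, seed = as.integer(seed))
}

#' Generate a synthetic cohort of phantom subjects
#'
#' Draws one phantom slice per subject with a target IMAT fraction sampled
#' uniformly inside its severity band (mild 0-33%, moderate 34-66%, severe
#' 67-100%, capped at 0.95 so viable muscle remains), simulates its MESE
#' acquisition, and optionally writes per-subject NIfTI echo stacks, truth
#' files and a CSV manifest.
#'
#' @param n_subjects Number of subjects.
#' @param severity_mix Named counts for `mild`, `moderate`, `severe`; must sum
#'   to `n_subjects`.
#' @param out_dir Output directory, or `NULL` to keep the cohort in memory.
#' @param seed Integer master seed; per-subject seeds derive from it.
#' @param shape,anatomy,texture_scale Passed to [make_phantom()].
#' @param protocol,dictionary Acquisition protocol and matched dictionary.
#' @param snr Acquisition SNR passed to [simulate_mese()] (default 50).
#' @return Invisibly, a list with `manifest` (data.frame: subject_id,
#'   severity, imat_fraction_true, seed) and `subjects` (list of
#'   `list(truth, series)`).
#' @export
make_cohort <- function(n_subjects, severity_mix, out_dir = NULL, seed = 1L,
                        shape = 128L, anatomy = "calf", texture_scale = 4,
                        protocol = mese_protocol(),
                        dictionary = build_dictionary(protocol), snr = 50) {
  severity_mix <- severity_mix[c("mild", "moderate", "severe")]
  severity_mix[is.na(severity_mix)] <- 0L
  names(severity_mix) <- c("mild", "moderate", "severe")
  if (sum(severity_mix) != n_subjects) {
    stop("`severity_mix` counts must sum to `n_subjects`", call. = FALSE)
  }
  bands <- list(mild = c(0, 0.33), moderate = c(0.34, 0.66), severe = c(0.67, 0.95))
  severities <- rep(names(severity_mix), times = severity_mix)
  targets <- with_seed(child_seed(seed, 1L), {
    vapply(severities, function(s) stats::runif(1, bands[[s]][1], bands[[s]][2]), 0)
  })
  subjects <- vector("list", n_subjects)
  manifest <- data.frame(subject_id = sprintf("sub-%02d", seq_len(n_subjects)),
                         severity = severities,
                         imat_fraction_true = NA_real_,
                         seed = vapply(seq_len(n_subjects),
                                       function(i) child_seed(seed, 100L + i), 0L),
                         stringsAsFactors = FALSE)
  for (i in seq_len(n_subjects)) {
    truth <- make_phantom(shape, anatomy, targets[i], seed = manifest$seed[i],
                          texture_scale = texture_scale)
    series <- simulate_mese(truth, protocol, dictionary, snr = snr,
                            seed = child_seed(manifest$seed[i], 7L))
    manifest$imat_fraction_true[i] <- truth$imat_fraction_true
    subjects[[i]] <- list(truth = truth, series = series)
  }
  if (!is.null(out_dir)) {
    ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(out_dir)) stop(sprintf("cannot create `out_dir` %s", out_dir), call. = FALSE)
    for (i in seq_len(n_subjects)) {
      id <- manifest$subject_id[i]
      RNifti::writeNifti(RNifti::asNifti(subjects[[i]]$series$data),
                         file.path(out_dir, paste0(id, "_echo.nii.gz")))
      saveRDS(subjects[[i]]$truth, file.path(out_dir, paste0(id, "_truth.rds")))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  invisible(list(manifest = manifest, subjects = subjects))
}
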