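# Preprocessing: receive-bias correction, anatomy cropping, input normalization.

#' Correct the multiplicative receive-field (B1-) bias
#'
#' Estimates a smooth multiplicative intensity field from the echo-summed
#' image by fitting a low-order 2-D polynomial to the log-intensity of
#' foreground pixels, iterated with robust outlier down-weighting so tissue
#' contrast is treated as outlier structure rather than bias. Every echo is
#' divided by the estimated field, which is normalized to mean 1 over the
#' foreground so global scale is preserved. The estimator is a projection in
#' the log domain, making the correction idempotent up to the reweighting.
#'
#' @param series An [echo_series()] of non-negative magnitude images.
#' @param degree Polynomial degree of the field model (default 3).
#' @param n_iter Robust reweighting iterations (default 5).
#' @param foreground Optional logical image; by default pixels whose
#'   echo-summed intensity exceeds 5% of its 99th percentile.
#' @param field_estimator Optional function `(log_image, foreground) ->
#'   log_field` substituting the built-in estimator, e.g. to plug in an
#'   external N4-style implementation.
#' @return A list with `series` (corrected [echo_series()]),
#'   `bias_field_estimate` (image, mean 1 over foreground) and `foreground`.
#' @export
correct_receiver_bias <- function(series, degree = 3, n_iter = 5,
                                  foreground = NULL, field_estimator = NULL) {
  stopifnot(inherits(series, "echo_series"))
  x <- series$data
  if (all(x == 0)) stop("all-zero input: nothing to correct", call. = FALSE)
  if (any(x < 0)) stop("magnitude inputs must be non-negative", call. = FALSE)
  esum <- apply(x, c(1, 2), sum)
  if (is.null(foreground)) {
    foreground <- esum > 0.05 * stats::quantile(esum, 0.99, names = FALSE)
  }
  if (sum(foreground) < 30L) stop("too few foreground pixels for field estimation", call. = FALSE)
  logs <- log(pmax(esum, .Machine$double.eps))
  if (is.null(field_estimator)) {
    logf <- poly_field_fit(logs, foreground, degree = degree, n_iter = n_iter)
  } else {
    logf <- field_estimator(logs, foreground)
  }
  field <- exp(logf - mean(logf[foreground]))
  field <- field / mean(field[foreground])
  corrected <- sweep(x, c(1, 2), field, "/")
  out <- series
  out$data <- corrected
  list(series = out, bias_field_estimate = field, foreground = foreground)
}

# robust weighted polynomial surface fit in the log domain
poly_field_fit <- function(logs, foreground, degree = 3, n_iter = 5) {
  h <- nrow(logs); w <- ncol(logs)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  rr <- matrix(seq_len(h), h, w)
  u <- (cc - (w + 1) / 2) / (w / 2)
  v <- (rr - (h + 1) / 2) / (h / 2)
  basis <- list(matrix(1, h, w))
  for (dsum in 1:degree) {
    for (i in 0:dsum) basis[[length(basis) + 1L]] <- u^(dsum - i) * v^i
  }
  X <- vapply(basis, function(b) b[foreground], numeric(sum(foreground)))
  y <- logs[foreground]
  wts <- rep(1, length(y))
  beta <- NULL
  for (it in seq_len(n_iter)) {
    fit <- stats::lm.wfit(X, y, wts)
    beta <- fit$coefficients
    r <- y - X %*% beta
    s <- stats::mad(r, center = 0)
    if (s < .Machine$double.eps) break
    # Tukey bisquare weights: tissue structure far from the smooth trend is ignored
    wts <- pmax(0, 1 - (r / (4.685 * s))^2)^2
  }
  beta[is.na(beta)] <- 0
  Reduce(`+`, Map(function(b, co) co * b, basis, as.list(beta)))
}

#' Detect the anatomy, crop around it and resize
#'
#' Separates the anatomy from background with an edge-based detector on the
#' first echo (gradient magnitude thresholded at a median-based automatic
#' level), closes and hole-fills the edge map to a single foreground
#' component, takes the tight bounding box with a 2-pixel margin, and resizes
#' all channels to `out_size` (bilinear for images, nearest-neighbor for
#' masks).
#'
#' @param stack Numeric array `H x W x C` (channels share one grid; an
#'   [echo_series()] data array works directly) or a single `H x W` matrix.
#' @param masks Optional named list of logical images cropped and resized
#'   alongside with nearest-neighbor interpolation.
#' @param out_size Output side length in pixels (default 128).
#' @param margin Bounding-box margin in pixels (default 2).
#' @return A list with `stack` (resized array), `masks`, `crop_bbox`
#'   (row0, col0, row1, col1; half-open, 0-based by convention of
#'   `(r0, c0)` inclusive / `(r1, c1)` exclusive) and `foreground`.
#' @export
crop_and_resize <- function(stack, masks = NULL, out_size = 128L, margin = 2L) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  h <- dim(stack)[1]; w <- dim(stack)[2]
  fg <- detect_foreground(stack[, , 1L])
  if (!any(fg)) stop("no foreground found: image appears empty", call. = FALSE)
  rows <- range(which(rowSums(fg) > 0))
  cols <- range(which(colSums(fg) > 0))
  r0 <- max(1L, rows[1] - margin); r1 <- min(h, rows[2] + margin)
  c0 <- max(1L, cols[1] - margin); c1 <- min(w, cols[2] + margin)
  resize_bl <- function(m) {
    as.matrix(EBImage::resize(EBImage::Image(m[r0:r1, c0:c1]),
                              w = out_size, h = out_size, filter = "bilinear"))
  }
  resize_nn <- function(m) {
    as.matrix(EBImage::resize(EBImage::Image(m[r0:r1, c0:c1] * 1),
                              w = out_size, h = out_size, filter = "none")) > 0.5
  }
  out <- array(0, dim = c(out_size, out_size, dim(stack)[3]))
  for (k in seq_len(dim(stack)[3])) out[, , k] <- resize_bl(stack[, , k])
  out_masks <- if (is.null(masks)) NULL else lapply(masks, resize_nn)
  list(stack = out, masks = out_masks,
       crop_bbox = c(r0 = r0 - 1L, c0 = c0 - 1L, r1 = r1, c1 = c1),
       foreground = fg)
}

# gradient-magnitude edge detection with automatic threshold, closed and
# hole-filled to one foreground component
detect_foreground <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(EBImage::Image(img), kx))
  gy <- as.matrix(EBImage::filter2(EBImage::Image(img), t(kx)))
  g <- sqrt(gx^2 + gy^2)
  pos <- g[g > 0]
  if (!length(pos)) return(matrix(FALSE, nrow(img), ncol(img)))
  thr <- 2 * stats::median(pos)
  edges <- g > thr
  if (!any(edges)) return(matrix(FALSE, nrow(img), ncol(img)))
  brush <- EBImage::makeBrush(5, shape = "box")
  closed <- EBImage::closing(EBImage::Image(edges * 1), brush)
  filled <- EBImage::fillHull(closed)
  lab <- EBImage::bwlabel(filled)
  tab <- tabulate(as.integer(lab[lab > 0]))
  if (!length(tab)) return(matrix(FALSE, nrow(img), ncol(img)))
  as.matrix(lab) == which.max(tab)
}

#' Clip and z-score an input map
#'
#' Clips intensities above the given percentile of the image's dynamic range
#' (computed over the whole image, background included), then normalizes to
#' zero mean and unit variance. Returns the constants actually applied so the
#' transform is reproducible.
#'
#' @param map Numeric image.
#' @param clip_percentile Upper clipping percentile (default 98).
#' @return A list with `map` (normalized image), `clip_value`, `mean`, `sd`.
#' @export
normalize_input <- function(map, clip_percentile = 98) {
  if (!all(is.finite(map))) stop("`map` must be finite", call. = FALSE)
  cv <- stats::quantile(map, clip_percentile / 100, names = FALSE)
  clipped <- pmin(map, cv)
  mu <- mean(clipped); sd <- stats::sd(as.vector(clipped))
  if (sd < .Machine$double.eps) {
    stop("zero variance after clipping: constant image cannot be z-scored", call. = FALSE)
  }
  list(map = (clipped - mu) / sd, clip_value = cv, mean = mu, sd = sd)
}
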