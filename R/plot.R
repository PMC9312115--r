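# Base-graphics visualization of phantoms, maps and label maps.

img_show <- function(m, main = "", col = grDevices::gray.colors(256), ...) {
  graphics::image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE, main = main,
                  col = col, useRaster = TRUE, ...)
}

#' Display a phantom's tissue mask and fat fraction
#' @param x A [make_phantom()] result.
#' @param ... Unused.
#' @export
plot.phantom_truth <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  img_show(x$tissue_mask, main = sprintf("%s tissue codes", x$anatomy),
           col = c("black", "gold", "firebrick", "white", "grey40", "wheat"))
  img_show(x$fat_fraction, main = "fat fraction")
  invisible(x)
}

#' Display fitted parametric maps
#' @param x A [fit_t2_pd()] result.
#' @param ... Unused.
#' @export
plot.parametric_maps <- function(x, ...) {
  k <- if (is.null(x$fat_fraction)) 2L else 3L
  op <- graphics::par(mfrow = c(1, k), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  t2 <- x$t2; t2[is.na(t2)] <- 0
  img_show(t2, main = "T2 [ms]")
  pd <- x$pd; pd[is.na(pd)] <- 0
  img_show(pd, main = "PD [a.u.]")
  if (k == 3L) {
    ff <- x$fat_fraction; ff[is.na(ff)] <- 0
    img_show(ff, main = "fat fraction")
  }
  invisible(x)
}

#' Display a tissue label map
#' @param x A [tissue_label_map()].
#' @param ... Unused.
#' @export
plot.tissue_label_map <- function(x, ...) {
  img_show(x$labels, main = "tissue labels (white viable, grey IMAT)",
           col = c("black", "white", "grey55"))
  invisible(x)
}

#' Scatter plot of biomarker agreement
#'
#' Ground-truth vs predicted IMAT fractions with the fitted regression line.
#'
#' @param gt_fractions,pred_fractions Cohort fraction vectors.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_biomarker_agreement <- function(gt_fractions, pred_fractions, ...) {
  ag <- cohort_agreement(gt_fractions, pred_fractions)
  graphics::plot(gt_fractions, pred_fractions, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "IMAT fraction (ground truth)",
                 ylab = "IMAT fraction (predicted)",
                 main = sprintf("r = %.3f, slope = %.2f", ag$pearson_r, ag$slope),
                 pch = 19, ...)
  graphics::abline(ag$intercept, ag$slope, col = "firebrick")
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(ag)
}
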