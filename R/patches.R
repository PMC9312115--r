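# Patch extraction for the weakly supervised tissue clustering stage.

PATCH_SIZE <- 16L
PATCH_HALF_LO <- 8L   # rows r-8 .. r+7: even window centered at index 8
PATCH_HALF_HI <- 7L

# erosion of a logical mask with the 16x16 square structuring element under
# the package's even-window convention (center at offset 8), via integral image
erode_patch_window <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- t(apply(apply(mask * 1, 2L, cumsum), 1L, cumsum))
  out <- matrix(FALSE, h, w)
  rr <- (PATCH_HALF_LO + 1L):(h - PATCH_HALF_HI)
  cc <- (PATCH_HALF_LO + 1L):(w - PATCH_HALF_HI)
  if (!length(rr) || !length(cc)) return(out)
  r0 <- rr - PATCH_HALF_LO; r1 <- rr + PATCH_HALF_HI
  c0 <- cc - PATCH_HALF_LO; c1 <- cc + PATCH_HALF_HI
  win <- S[r1 + 1L, c1 + 1L] - S[r0, c1 + 1L] - S[r1 + 1L, c0] + S[r0, c0]
  out[rr, cc] <- win == PATCH_SIZE^2
  out
}

#' Extract 16x16 two-channel patches from the muscle region
#'
#' Erodes the muscle-region mask with a 16x16 structuring element (so no
#' patch touches the region boundary) and crops one patch per remaining
#' positive pixel from the mask-multiplied T2 and PD maps, centered on that
#' pixel with the even-window convention rows `r-8 .. r+7`. Weak labels are
#' copied from the label map at each center pixel when provided (1 = viable
#' muscle, 0 = IMAT, following the labeling convention of the triplet
#' sampler).
#'
#' @param t2,pd Images sharing one grid.
#' @param muscle_mask Logical muscle-region image.
#' @param weak_label_map Optional [tissue_label_map()] supplying weak labels.
#' @return An object of class `patch_set`: `patches` (`16 x 16 x 2 x M`),
#'   `centers` (`M x 2` row/col), `weak_labels` (`M`, in {0, 1} or `NA`),
#'   `eroded_mask`, `muscle_mask`.
#' @export
extract_patches <- function(t2, pd, muscle_mask, weak_label_map = NULL) {
  stopifnot(identical(dim(t2), dim(muscle_mask)),
            identical(dim(pd), dim(muscle_mask)))
  eroded <- erode_patch_window(muscle_mask == TRUE)
  if (!any(eroded)) {
    stop(sprintf(paste("muscle region vanishes under 16x16 erosion;",
                       "the region must contain at least one full %dx%d window"),
                 PATCH_SIZE, PATCH_SIZE), call. = FALSE)
  }
  t2m <- t2 * muscle_mask
  pdm <- pd * muscle_mask
  centers <- which(eroded, arr.ind = TRUE)
  m <- nrow(centers)
  patches <- array(0, dim = c(PATCH_SIZE, PATCH_SIZE, 2L, m))
  for (i in seq_len(m)) {
    r <- centers[i, 1L]; c <- centers[i, 2L]
    rows <- (r - PATCH_HALF_LO):(r + PATCH_HALF_HI)
    cols <- (c - PATCH_HALF_LO):(c + PATCH_HALF_HI)
    patches[, , 1L, i] <- t2m[rows, cols]
    patches[, , 2L, i] <- pdm[rows, cols]
  }
  labels <- rep(NA_integer_, m)
  if (!is.null(weak_label_map)) {
    stopifnot(inherits(weak_label_map, "tissue_label_map"))
    lab <- weak_label_map$labels[centers]
    labels <- ifelse(lab == LABEL_VIABLE, 1L, ifelse(lab == LABEL_IMAT, 0L, NA_integer_))
  }
  structure(list(patches = patches, centers = unname(centers),
                 weak_labels = labels, eroded_mask = eroded,
                 muscle_mask = muscle_mask == TRUE),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  nl <- sum(!is.na(x$weak_labels))
  cat(sprintf("patch_set: %d patches (16x16x2), %d weakly labeled (%d viable / %d IMAT)\n",
              dim(x$patches)[4], nl, sum(x$weak_labels == 1L, na.rm = TRUE),
              sum(x$weak_labels == 0L, na.rm = TRUE)))
  invisible(x)
}

# concatenate patch sets from several slices
combine_patch_sets <- function(sets) {
  m <- sum(vapply(sets, function(s) dim(s$patches)[4], 0L))
  patches <- array(0, dim = c(PATCH_SIZE, PATCH_SIZE, 2L, m))
  centers <- matrix(0L, m, 2L)
  labels <- rep(NA_integer_, m)
  src <- integer(m)
  at <- 0L
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    mk <- dim(s$patches)[4]
    patches[, , , at + seq_len(mk)] <- s$patches
    centers[at + seq_len(mk), ] <- s$centers
    labels[at + seq_len(mk)] <- s$weak_labels
    src[at + seq_len(mk)] <- k
    at <- at + mk
  }
  structure(list(patches = patches, centers = centers, weak_labels = labels,
                 source_slice = src),
            class = "patch_set")
}

#' Sample an (anchor, positive, negative) patch triplet
#'
#' The anchor is drawn uniformly from all patches; the positive uniformly
#' from the anchor's weak-label class excluding the anchor itself; the
#' negative uniformly from the other class.
#'
#' @param patchset A [extract_patches()] result with both classes labeled.
#' @param seed Integer seed; the triple is reproducible.
#' @return List with indices `anchor`, `positive`, `negative` and the
#'   corresponding `16 x 16 x 2` patch arrays.
#' @export
sample_triplet <- function(patchset, seed = 1L) {
  lab <- patchset$weak_labels
  if (!any(lab == 0L, na.rm = TRUE) || !any(lab == 1L, na.rm = TRUE)) {
    stop("both weak-label classes must be present to sample triplets", call. = FALSE)
  }
  idx <- with_seed(seed, sample_triplet_indices(lab, 1L))
  list(anchor = idx$a, positive = idx$p, negative = idx$n,
       anchor_patch = patchset$patches[, , , idx$a],
       positive_patch = patchset$patches[, , , idx$p],
       negative_patch = patchset$patches[, , , idx$n])
}

# vectorized triplet index sampling under the current RNG stream
sample_triplet_indices <- function(labels, n) {
  labeled <- which(!is.na(labels))
  a <- labeled[sample.int(length(labeled), n, replace = TRUE)]
  p <- integer(n); ng <- integer(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[a[i]])
    same <- same[same != a[i]]
    if (!length(same)) same <- a[i]  # singleton class: degenerate positive
    other <- which(labels == (1L - labels[a[i]]))
    p[i] <- same[sample.int(length(same), 1L)]
    ng[i] <- other[sample.int(length(other), 1L)]
  }
  list(a = a, p = p, n = ng)
}
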