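# Evaluation metrics: Dice overlap, clustering accuracy, NMI, ARI.

#' Dice similarity coefficient
#'
#' `2 |X intersect Y| / (|X| + |Y|)`. When both masks are empty the score is
#' defined as 1.0 (degenerate slices agree perfectly by convention).
#'
#' @param x,y Logical (or 0/1) masks of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("mask shapes differ", call. = FALSE)
  x <- x == TRUE | x == 1; y <- y == TRUE | y == 1
  sx <- sum(x); sy <- sum(y)
  if (sx + sy == 0L) return(1.0)
  2 * sum(x & y) / (sx + sy)
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return Scalar in `[0, 1]`.
#' @export
accuracy <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- tp + tn + fp + fn
  if (total == 0) stop("total count must be positive", call. = FALSE)
  (tp + tn) / total
}

# contingency table of two partitions (integer-coded)
partition_table <- function(a, b) {
  if (length(a) != length(b)) stop("partition lengths differ", call. = FALSE)
  table(factor(a), factor(b))
}

#' Normalized mutual information of two partitions
#'
#' Mutual information normalized by the arithmetic mean of the two partition
#' entropies (the normalization choice is part of the score's definition and
#' is stated here so values are comparable across tools). Invariant to
#' cluster relabeling; 0 for independent partitions, 1 for identical ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  tab <- partition_table(a, b)
  n <- sum(tab)
  if (n == 0L) stop("empty partitions", call. = FALSE)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  sel <- pij > 0
  mi <- sum(pij[sel] * log(pij[sel] / (pi_[row(pij)[sel]] * pj_[col(pij)[sel]])))
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  denom <- (ha + hb) / 2
  if (denom < .Machine$double.eps) return(0)
  max(0, min(1, mi / denom))
}

#' Adjusted Rand index of two partitions
#'
#' Pair-counting agreement with correction for chance via the standard
#' hypergeometric expectation; ~0 for random labelings, exactly 1 for
#' identical partitions up to relabeling.
#'
#' @param a,b Cluster label vectors of equal length (>= 2).
#' @return Scalar in `(-1, 1]`.
#' @export
ari <- function(a, b) {
  if (length(a) < 2L) stop("need at least 2 items", call. = FALSE)
  tab <- partition_table(a, b)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < .Machine$double.eps) return(ifelse(sum_ij == maxi, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

#' Clustering accuracy of a binary label assignment
#'
#' Fraction of items whose predicted label matches the reference after the
#' cluster-to-label mapping. `matching = "majority"` assumes `pred` already
#' carries tissue labels from the majority-vote mapping (the primary
#' convention); `matching = "optimal"` additionally permits the label swap
#' that maximizes agreement.
#'
#' @param pred,truth Binary label vectors (same coding) of equal length.
#' @param matching `"majority"` or `"optimal"`.
#' @return Scalar in `[0, 1]`.
#' @export
clustering_accuracy <- function(pred, truth, matching = c("majority", "optimal")) {
  matching <- match.arg(matching)
  if (length(pred) != length(truth)) stop("length mismatch", call. = FALSE)
  acc <- mean(pred == truth)
  if (matching == "optimal") acc <- max(acc, mean(pred != truth))
  acc
}

#' Stage-2 evaluation of a label map against ground truth
#'
#' Computes per-class Dice (viable muscle, IMAT), clustering accuracy, NMI
#' and ARI over the pixels of the evaluation mask.
#'
#' @param pred,truth [tissue_label_map()] objects on one grid.
#' @param mask Logical evaluation mask (default: the truth muscle mask).
#' @return A one-row data.frame with columns `dice_viable`, `dice_imat`,
#'   `acc`, `nmi`, `ari`.
#' @export
evaluate_labels <- function(pred, truth, mask = truth$muscle_mask) {
  pv <- pred$labels[mask]; tv <- truth$labels[mask]
  data.frame(
    dice_viable = dice(pred$labels == LABEL_VIABLE & mask,
                       truth$labels == LABEL_VIABLE & mask),
    dice_imat = dice(pred$labels == LABEL_IMAT & mask,
                     truth$labels == LABEL_IMAT & mask),
    acc = clustering_accuracy(pv, tv),
    nmi = nmi(pv, tv),
    ari = ari(pv, tv)
  )
}
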