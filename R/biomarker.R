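# The IMAT-fraction disease biomarker and cohort-level agreement.

#' IMAT fraction of a label map
#'
#' The biomarker: the number of IMAT-labeled pixels divided by the number of
#' muscle-region pixels (viable + IMAT).
#'
#' @param labels A [tissue_label_map()].
#' @return Scalar fraction in `[0, 1]`.
#' @export
imat_fraction <- function(labels) {
  stopifnot(inherits(labels, "tissue_label_map"))
  muscle <- sum(labels$labels == LABEL_VIABLE) + sum(labels$labels == LABEL_IMAT)
  if (muscle == 0L) stop("empty muscle region: the biomarker is undefined", call. = FALSE)
  sum(labels$labels == LABEL_IMAT) / muscle
}

#' Severity class of an IMAT fraction
#'
#' Bands the fraction into mild (0-33%), moderate (34-66%) or severe
#' (67-100%) disease. Continuous cutpoints at 1/3 and 2/3 are used
#' (upper-inclusive for mild and moderate) so every fraction in `[0, 1]` is
#' assigned a class.
#'
#' @param fraction IMAT fraction in `[0, 1]` (vectorized).
#' @return Character vector: `"mild"`, `"moderate"` or `"severe"`.
#' @export
severity_class <- function(fraction) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1)) {
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  }
  ifelse(fraction <= 1 / 3, "mild", ifelse(fraction <= 2 / 3, "moderate", "severe"))
}

#' Biomarker report for one slice
#'
#' @param labels A [tissue_label_map()].
#' @param subject_id Identifier recorded in the report.
#' @return One-row data.frame: `subject_id`, `imat_area`, `muscle_area`,
#'   `imat_fraction`, `severity`.
#' @export
biomarker_report <- function(labels, subject_id = NA_character_) {
  fr <- imat_fraction(labels)
  data.frame(subject_id = subject_id,
             imat_area = sum(labels$labels == LABEL_IMAT),
             muscle_area = sum(labels$labels %in% c(LABEL_VIABLE, LABEL_IMAT)),
             imat_fraction = fr,
             severity = severity_class(fr),
             stringsAsFactors = FALSE)
}

#' Agreement between ground-truth and predicted biomarkers
#'
#' Ordinary least-squares regression of predicted on true IMAT fractions and
#' their Pearson correlation, as used to validate the biomarker at cohort
#' level.
#'
#' @param gt_fractions,pred_fractions Equal-length numeric vectors (>= 3).
#' @return List with `slope`, `intercept`, `pearson_r`, `n`.
#' @export
cohort_agreement <- function(gt_fractions, pred_fractions) {
  if (length(gt_fractions) != length(pred_fractions)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (length(gt_fractions) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (stats::sd(gt_fractions) < .Machine$double.eps) {
    stop("zero variance in ground-truth fractions", call. = FALSE)
  }
  fit <- stats::lm(pred_fractions ~ gt_fractions)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       pearson_r = stats::cor(gt_fractions, pred_fractions),
       n = length(gt_fractions))
}
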