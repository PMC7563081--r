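#' Segmentation agreement metrics
#'
#' Pixel-wise accuracy and mean intersection-over-union between a predicted
#' and a reference binary mask, the metrics used to validate automated
#' anterior-vertebral-line segmentation. Both are symmetric in their
#' arguments.
#'
#' `mean_iou()` averages IoU over the two classes (foreground line,
#' background); a class absent from both masks contributes 1.0 so the
#' metric stays defined on degenerate inputs.
#'
#' @param predicted,reference Same-shape logical or 0/1 matrices.
#' @return A scalar in `[0, 1]`.
#' @export
#' @examples
#' ref <- matrix(c(1, 1, 0, 0), 1)
#' pred <- matrix(c(1, 0, 0, 0), 1)
#' pixel_accuracy(pred, ref) # 3/4
#' mean_iou(pred, ref) # (1/2 + 2/3) / 2
pixel_accuracy <- function(predicted, reference) {
  check_mask_pair(predicted, reference)
  mean((predicted != 0) == (reference != 0))
}

#' @rdname pixel_accuracy
#' @export
mean_iou <- function(predicted, reference) {
  check_mask_pair(predicted, reference)
  p <- predicted != 0
  r <- reference != 0
  iou_class <- function(pc, rc) {
    uni <- sum(pc | rc)
    if (uni == 0) 1 else sum(pc & rc) / uni
  }
  (iou_class(p, r) + iou_class(!p, !r)) / 2
}

check_mask_pair <- function(predicted, reference) {
  if (!is.matrix(predicted) || !is.matrix(reference) ||
      !all(dim(predicted) == dim(reference))) {
    cc_abort("dimension", "Predicted and reference masks must be same-shape matrices.")
  }
  invisible(NULL)
}

#' Root-mean-squared error between paired measurements
#'
#' Agreement on the curvature-coefficient scale between two observers (or
#' an observer and an automated pipeline) measuring the same subjects.
#'
#' @param a,b Equal-length numeric vectors of curvature coefficients.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) cc_abort("dimension", "`a` and `b` must have equal length.")
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(c(a, b)))) {
    cc_abort("invalid_value", "Measurements must be finite numerics.")
  }
  sqrt(mean((a - b)^2))
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC — the
#' standard choice for method-agreement studies — computed from the two-way
#' ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with n subjects (rows) and k raters (columns).
#'
#' @param a,b Equal-length numeric measurement vectors from two raters on
#'   the same n >= 3 subjects, in subject order.
#' @return The ICC, a scalar in `(-1, 1]`.
#' @export
icc <- function(a, b) {
  if (length(a) != length(b)) cc_abort("dimension", "`a` and `b` must have equal length.")
  n <- length(a)
  if (n < 3) cc_abort("invalid_value", "ICC needs at least 3 subjects.")
  if (any(!is.finite(c(a, b)))) cc_abort("invalid_value", "Measurements must be finite.")
  m <- cbind(a, b)
  k <- 2L
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  if (sum((m - grand)^2) == 0) {
    cc_abort("undefined_icc", "Zero total variance; ICC undefined.")
  }
  ms_r <- k * sum((row_m - grand)^2) / (n - 1)
  ms_c <- n * sum((col_m - grand)^2) / (k - 1)
  ss_e <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k / n * (ms_c - ms_e))
}

#' Summarise segmentation and measurement agreement
#'
#' Convenience wrapper producing the validation report for a set of mask
#' pairs and paired coefficient measurements.
#'
#' @param mask_pairs List of `list(predicted =, reference =)` mask pairs
#'   (may be empty).
#' @param pairs Data frame with columns `a` and `b` of paired coefficients
#'   (may be `NULL`).
#' @return A one-row tibble: `pixel_accuracy`, `mean_iou` (means over
#'   pairs; `NA` if none), `rmse`, `icc` (`NA` if no paired measurements).
#' @export
metrics_report <- function(mask_pairs = list(), pairs = NULL) {
  pa <- miou <- NA_real_
  if (length(mask_pairs) > 0) {
    pa <- mean(vapply(mask_pairs, function(p) pixel_accuracy(p$predicted, p$reference), numeric(1)))
    miou <- mean(vapply(mask_pairs, function(p) mean_iou(p$predicted, p$reference), numeric(1)))
  }
  r <- ic <- NA_real_
  if (!is.null(pairs)) {
    r <- rmse(pairs$a, pairs$b)
    ic <- icc(pairs$a, pairs$b)
  }
  tibble(pixel_accuracy = pa, mean_iou = miou, rmse = r, icc = ic)
}
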