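# Confusion-matrix validation metrics for binary detections.

#' Confusion counts between a ground-truth and a predicted binary mask
#'
#' Superimposing truth and prediction yields four voxel categories:
#' `a` true negatives, `b` false positives, `c` false negatives, `d` true
#' positives.  Evaluation is restricted to `eval_mask` (typically the brain
#' mask, so background does not inflate `a`).
#'
#' @param truth,pred binary `Volume3D` masks on the same grid.
#' @param eval_mask logical array or binary `Volume3D`; default: all voxels.
#' @return An object of class `ConfusionCounts` (list `a`, `b`, `c`, `d`).
#' @export
confusion_counts <- function(truth, pred, eval_mask = NULL) {
  if (!inherits(truth, "Volume3D") || !inherits(pred, "Volume3D"))
    stop("truth and pred must be Volume3D masks")
  stop_if_grid_mismatch(truth, pred, "truth and pred")
  tt <- truth$data > 0.5
  pp <- pred$data > 0.5
  if (is.null(eval_mask)) {
    em <- rep(TRUE, length(tt))
  } else {
    em <- if (inherits(eval_mask, "Volume3D")) eval_mask$data > 0.5 else eval_mask
    if (length(em) != length(tt)) stop("eval_mask must match the mask grid")
  }
  tt <- tt[em]; pp <- pp[em]
  structure(list(a = sum(!tt & !pp), b = sum(!tt & pp),
                 c = sum(tt & !pp), d = sum(tt & pp)),
            class = "ConfusionCounts")
}

#' The seven detection metrics from confusion counts
#'
#' true positive rate `d/(c+d)`, true negative rate `a/(a+b)`, false positive
#' rate `b/(a+b)`, false negative rate `c/(c+d)`, precision `d/(b+d)`,
#' accuracy `(a+d)/(a+b+c+d)` and Dice
#' `2 * precision * tpr / (precision + tpr)` (algebraically `2d/(2d+b+c)`).
#' Ratios with zero denominator are returned as `NA` (undefined), not 0 —
#' except Dice, which is defined as `2d/(2d+b+c)` whenever `2d+b+c > 0`.
#'
#' @param cc a [confusion_counts()] result, or a list with fields a, b, c, d.
#' @return An object of class `DetectionMetrics` (list of the seven ratios).
#' @export
detection_metrics <- function(cc) {
  a <- cc$a; b <- cc$b; c_ <- cc$c; d <- cc$d
  if (any(c(a, b, c_, d) < 0)) stop("confusion counts must be non-negative")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  tpr <- rat(d, c_ + d)
  tnr <- rat(a, a + b)
  prec <- rat(d, b + d)
  dice <- if (!is.na(tpr) && !is.na(prec) && (prec + tpr) > 0)
    2 * prec * tpr / (prec + tpr)
  else rat(2 * d, 2 * d + b + c_)
  structure(list(tpr = tpr, tnr = tnr,
                 fpr = rat(b, a + b), fnr = rat(c_, c_ + d),
                 precision = prec,
                 accuracy = rat(a + d, a + b + c_ + d),
                 dice = dice),
            class = "DetectionMetrics")
}

#' @export
print.DetectionMetrics <- function(x, ...) {
  cat(sprintf(
    "tpr %.4f  tnr %.4f  fpr %.4f  fnr %.4f  precision %.4f  accuracy %.4f  dice %.4f\n",
    x$tpr, x$tnr, x$fpr, x$fnr, x$precision, x$accuracy, x$dice))
  invisible(x)
}
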