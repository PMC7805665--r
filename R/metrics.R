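# Segmentation evaluation: per-class precision, recall and dice on the
# [0, 100] scale, and the composite dice (unweighted mean over foreground
# classes) used to rank multi-class tumor-segmentation results.

mask_array <- function(x) {
  if (inherits(x, "ct_labelmask")) x$labels else as.array(x)
}

#' Voxel-wise confusion counts for one class
#'
#' Binarizes both masks as class-vs-rest and counts agreement.
#'
#' @param pred predicted labels ([ct_labelmask] or integer array).
#' @param truth reference labels, same shape.
#' @param class_id the class evaluated.
#' @return List with `TP`, `FP`, `FN`, `TN` (their sum is the voxel count).
#' @export
confusion_counts <- function(pred, truth, class_id) {
  p <- mask_array(pred); t <- mask_array(truth)
  if (!all(dim(p) == dim(t))) stop("prediction and truth shapes differ")
  if (inherits(truth, "ct_labelmask") && !class_id %in% truth$class_set)
    stop("class ", class_id, " not in the mask's class set")
  pb <- p == class_id; tb <- t == class_id
  structure(list(TP = sum(pb & tb), FP = sum(pb & !tb),
                 FN = sum(!pb & tb), TN = sum(!pb & !tb)),
            class = "confusion_counts")
}

#' Precision and recall from confusion counts
#'
#' `P = TP/(TP+FP) * 100`, `R = TP/(TP+FN) * 100`.  An empty denominator
#' (no positive predictions, or no positive reference voxels) yields 0 and
#' sets the corresponding entry of the `undefined` flag.
#'
#' @param counts a `confusion_counts` object.
#' @return List with `precision`, `recall` (each in `[0, 100]`) and a
#'   logical `undefined` flag vector.
#' @export
precision_recall <- function(counts) {
  pu <- counts$TP + counts$FP == 0
  ru <- counts$TP + counts$FN == 0
  if (pu) warning("no positive predictions; precision reported as 0")
  if (ru) warning("no positive reference voxels; recall reported as 0")
  list(precision = if (pu) 0 else 100 * counts$TP / (counts$TP + counts$FP),
       recall = if (ru) 0 else 100 * counts$TP / (counts$TP + counts$FN),
       undefined = c(precision = pu, recall = ru))
}

#' Dice overlap score for one class
#'
#' `D = 2 |U intersect V| / (|U| + |V|) * 100` for the binarized masks.
#' When both masks are empty the overlap is vacuously perfect: 100 is
#' returned with a warning (flagged via attribute `undefined`).
#'
#' @inheritParams confusion_counts
#' @return Scalar in `[0, 100]`.
#' @export
dice_score <- function(pred, truth, class_id) {
  p <- mask_array(pred) == class_id
  t <- mask_array(truth) == class_id
  if (!all(dim(p) == dim(t))) stop("prediction and truth shapes differ")
  su <- sum(p); sv <- sum(t)
  if (su + sv == 0) {
    warning("class ", class_id, " absent from both masks; dice reported as 100")
    return(structure(100, undefined = TRUE))
  }
  200 * sum(p & t) / (su + sv)
}

#' Composite dice
#'
#' Unweighted arithmetic mean of foreground-class dice scores, the
#' aggregate used to rank organ+tumor segmentations.  Reporting uses
#' decimal half-up rounding (see [round_half_up()]) so values recomputed
#' from printed per-class scores match their printed composites.
#'
#' @param per_class_dices numeric vector of foreground-class dice scores.
#' @param digits decimal places for the rounded value (`NULL` for none).
#' @return The mean, rounded to `digits` if requested.
#' @export
composite_dice <- function(per_class_dices, digits = 2) {
  if (length(per_class_dices) == 0L) stop("need at least one dice value")
  m <- mean(as.numeric(per_class_dices))
  if (is.null(digits)) m else round_half_up(m, digits)
}

#' Evaluate a predicted segmentation against a reference
#'
#' Computes per-class precision, recall and dice plus the composite dice
#' over the foreground classes.
#'
#' @param pred predicted [ct_labelmask] (or integer array).
#' @param truth reference mask, same geometry.
#' @param classes foreground class ids to evaluate (default `1:2`,
#'   organ and tumor).
#' @return A `metrics_report`: list with `per_class` (data.frame of class,
#'   precision, recall, dice) and `composite_dice` (unrounded).
#' @export
evaluate_case <- function(pred, truth, classes = 1:2) {
  rows <- lapply(classes, function(cl) {
    cc <- confusion_counts(pred, truth, cl)
    pr <- suppressWarnings(precision_recall(cc))
    d <- suppressWarnings(dice_score(pred, truth, cl))
    data.frame(class = cl, precision = pr$precision, recall = pr$recall,
               dice = as.numeric(d))
  })
  per_class <- do.call(rbind, rows)
  structure(list(per_class = per_class,
                 composite_dice = composite_dice(per_class$dice, digits = NULL)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- x$per_class
  df[-1] <- lapply(df[-1], function(v) sprintf("%.2f", v))
  print(df, row.names = FALSE)
  cat(sprintf("composite dice: %.2f\n", round_half_up(x$composite_dice, 2)))
  invisible(x)
}
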