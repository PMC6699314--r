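#' Per-class Dice coefficient
#'
#' `Dice = 2|Y_k intersect T_k| / (|Y_k| + |T_k|)` for the pixels predicted
#' and labeled as class `k`. Empty-set rule: if the class is absent from
#' both maps the value is the sentinel `NA` ("excluded", not counted in
#' means); if it is absent from exactly one, the value is 0.
#'
#' @param pred predicted [label_map()].
#' @param truth ground-truth [label_map()].
#' @param k class value (2 = RV, 3 = myocardium, 4 = LV; background is not
#'   scored).
#' @return scalar in \[0, 1\], or `NA` when excluded.
#' @export
dice_coefficient <- function(pred, truth, k) {
  check_same_shape(pred, truth, "pred and truth")
  y <- pred == k
  t <- truth == k
  ny <- sum(y); nt <- sum(t)
  if (ny == 0 && nt == 0) return(NA_real_)
  2 * sum(y & t) / (ny + nt)
}

#' Per-class intersection over union
#'
#' `IoU = |Y_k intersect T_k| / |Y_k union T_k|` with the same empty-set
#' rules as [dice_coefficient()]. Related to Dice by
#' `IoU = Dice / (2 - Dice)`.
#'
#' @inheritParams dice_coefficient
#' @return scalar in \[0, 1\], or `NA` when excluded.
#' @export
iou <- function(pred, truth, k) {
  check_same_shape(pred, truth, "pred and truth")
  y <- pred == k
  t <- truth == k
  u <- sum(y | t)
  if (u == 0) return(NA_real_)
  sum(y & t) / u
}

#' Evaluate predicted segmentations against ground truth
#'
#' Computes per-image, per-class Dice and IoU for the three foreground
#' structures (RV = 2, myocardium = 3, LV = 4) and aggregates them by
#' unweighted mean over the included (not both-empty) entries, mirroring
#' the usual per-structure reporting of cardiac segmentation studies.
#'
#' @param preds list of predicted [label_map()]s.
#' @param truths list of ground-truth [label_map()]s, same length.
#' @param classes class values to score (default `c(2, 3, 4)`).
#' @return a `metrics_report`: list with `per_image` (long data.frame:
#'   image, class, dice, iou, n_pred, n_truth, n_overlap), `per_class`
#'   (class means and counts of excluded entries) and `mean_dice` /
#'   `mean_iou` (means of the per-class means over classes with at least
#'   one included entry).
#' @export
evaluate <- function(preds, truths, classes = c(2L, 3L, 4L)) {
  if (length(preds) == 0) stop("empty prediction list")
  if (length(preds) != length(truths))
    stop("prediction and truth lists differ in length")
  rows <- list()
  for (i in seq_along(preds)) {
    check_same_shape(preds[[i]], truths[[i]], "pred and truth")
    for (k in classes) {
      y <- preds[[i]] == k
      t <- truths[[i]] == k
      rows[[length(rows) + 1L]] <- data.frame(
        image = i, class = k,
        dice = dice_coefficient(preds[[i]], truths[[i]], k),
        iou = iou(preds[[i]], truths[[i]], k),
        n_pred = sum(y), n_truth = sum(t), n_overlap = sum(y & t))
    }
  }
  per_image <- do.call(rbind, rows)
  per_class <- do.call(rbind, lapply(classes, function(k) {
    d <- per_image[per_image$class == k, ]
    data.frame(class = k,
               dice = mean(d$dice, na.rm = TRUE),
               iou = mean(d$iou, na.rm = TRUE),
               n_included = sum(!is.na(d$dice)),
               n_excluded = sum(is.na(d$dice)))
  }))
  inc <- per_class$n_included > 0
  structure(list(per_image = per_image, per_class = per_class,
                 mean_dice = if (any(inc)) mean(per_class$dice[inc]) else NA_real_,
                 mean_iou = if (any(inc)) mean(per_class$iou[inc]) else NA_real_),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cls <- c("2" = "RV", "3" = "Myocardium", "4" = "LV")
  cat("Segmentation metrics (per-class means over included images):\n")
  for (i in seq_len(nrow(x$per_class))) {
    r <- x$per_class[i, ]
    cat(sprintf("  %-11s Dice %.3f  IoU %.3f  (n=%d, excluded=%d)\n",
                cls[as.character(r$class)], r$dice, r$iou,
                r$n_included, r$n_excluded))
  }
  cat(sprintf("  %-11s Dice %.3f  IoU %.3f\n", "Mean", x$mean_dice, x$mean_iou))
  invisible(x)
}

#' Write a metrics report as a delimited table
#'
#' @param report a `metrics_report` from [evaluate()].
#' @param path output TSV path.
#' @export
write_metrics <- function(report, path) {
  write.table(report$per_class, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
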