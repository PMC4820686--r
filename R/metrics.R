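#' Confusion counts between a predicted and a reference mask
#'
#' @param pred Predicted binary mask.
#' @param truth Reference (manual) binary mask of the same shape.
#' @return List of class \code{"confusion_counts"} with integer
#'   \code{TP}, \code{FP}, \code{FN}, \code{TN} summing to the pixel
#'   count.
#' @export
confusion <- function(pred, truth) {
  pred <- validate_mask(pred)
  truth <- validate_mask(truth)
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth shapes differ", call. = FALSE)
  structure(list(TP = sum(pred == 1L & truth == 1L),
                 FP = sum(pred == 1L & truth == 0L),
                 FN = sum(pred == 0L & truth == 1L),
                 TN = sum(pred == 0L & truth == 0L)),
            class = "confusion_counts")
}

#' Evaluation metrics from confusion counts
#'
#' Accuracy \code{(TP+TN)/total}, overlap (Jaccard)
#' \code{TP/(TP+FP+FN)}, sensitivity \code{TP/(TP+FN)} and specificity
#' \code{TN/(TN+FP)}. Degenerate 0/0 ratios resolve to 1: a metric whose
#' reference class is absent has nothing to miss.
#'
#' @param counts A \code{\link{confusion}} result.
#' @return Named list with the four metrics, all in \code{[0, 1]}.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    total <- TP + FP + FN + TN
    if (total == 0L) stop("empty masks", call. = FALSE)
    list(
      accuracy = (TP + TN) / total,
      overlap = if (TP + FP + FN == 0L) 1 else TP / (TP + FP + FN),
      sensitivity = if (TP + FN == 0L) 1 else TP / (TP + FN),
      specificity = if (TN + FP == 0L) 1 else TN / (TN + FP)
    )
  })
}

#' Evaluate a mask stack against ground truth
#'
#' Per-slice metrics plus both aggregations: pooled (confusion counts
#' summed over slices before computing metrics) and per-slice averaged.
#'
#' @param pred_masks,truth_masks Lists of binary masks, pairwise equal
#'   shape.
#' @return List: \code{per_slice} (data frame), \code{pooled},
#'   \code{averaged}, \code{pooled_counts}.
#' @export
evaluate_masks <- function(pred_masks, truth_masks) {
  if (length(pred_masks) != length(truth_masks))
    stop("pred and truth stacks have different lengths", call. = FALSE)
  per <- lapply(seq_along(pred_masks), function(i) {
    cm <- confusion(pred_masks[[i]], truth_masks[[i]])
    c(list(slice = i), cm[c("TP", "FP", "FN", "TN")], compute_metrics(cm))
  })
  per_df <- do.call(rbind, lapply(per, function(p) as.data.frame(p)))
  pooled_counts <- structure(
    list(TP = sum(per_df$TP), FP = sum(per_df$FP),
         FN = sum(per_df$FN), TN = sum(per_df$TN)),
    class = "confusion_counts")
  list(per_slice = per_df,
       pooled = compute_metrics(pooled_counts),
       averaged = as.list(colMeans(per_df[, c("accuracy", "overlap",
                                              "sensitivity", "specificity")])),
       pooled_counts = pooled_counts)
}
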