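# Confusion-matrix validation of stability predictions against
# experimental labels.

#' Confusion counts container
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return list of class \code{confusion_counts}.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || sum(counts) < 1)
    stop("confusion counts must be non-negative and sum to at least 1")
  obj <- as.list(counts)
  class(obj) <- "confusion_counts"
  obj
}

#' Sensitivity, specificity and false discovery rate
#'
#' sensitivity = tp/(tp+fn); specificity = tn/(tn+fp);
#' FDR = fp/(tp+fp), defined as 0 when nothing is predicted positive.
#' Metrics are reported rounded to 3 decimals.
#'
#' @param counts a \code{\link{confusion_counts}} (or list with tp, fp,
#'   tn, fn).
#' @return named numeric vector (sensitivity, specificity,
#'   false_discovery_rate).
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fn < 1) stop("sensitivity undefined: tp + fn = 0")
  if (tn + fp < 1) stop("specificity undefined: tn + fp = 0")
  fdr <- if (tp + fp == 0) 0 else fp / (tp + fp)
  round(c(sensitivity = tp / (tp + fn),
          specificity = tn / (tn + fp),
          false_discovery_rate = fdr), 3)
}

#' Tally predictions against experimental stability labels
#'
#' The positive class is experimentally stabilizing (ddG strictly below
#' zero); a mutation is predicted positive when its predicted value is at
#' or below \code{decision_threshold} (0 by default; move it to the
#' pipeline's stage thresholds to score thresholded cascades).
#'
#' @param predicted_ddg named numeric vector of predictions (kcal/mol).
#' @param experimental_ddg named numeric vector of measurements over the
#'   same mutation names.
#' @param decision_threshold prediction cutoff, inclusive (default 0).
#' @return a \code{\link{confusion_counts}}.
#' @export
classify_predictions <- function(predicted_ddg, experimental_ddg,
                                 decision_threshold = 0.0) {
  missing_exp <- setdiff(names(predicted_ddg), names(experimental_ddg))
  missing_pred <- setdiff(names(experimental_ddg), names(predicted_ddg))
  if (length(missing_exp) || length(missing_pred))
    stop("mutation keys differ between maps; missing: ",
         paste(c(missing_exp, missing_pred), collapse = ", "))
  exp_ <- experimental_ddg[names(predicted_ddg)]
  pred_pos <- predicted_ddg <= decision_threshold
  true_pos <- exp_ < 0
  confusion_counts(
    tp = sum(pred_pos & true_pos),
    fp = sum(pred_pos & !true_pos),
    tn = sum(!pred_pos & !true_pos),
    fn = sum(!pred_pos & true_pos)
  )
}
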