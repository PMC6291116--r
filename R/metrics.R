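# Instance-level detection metrics: greedy IoU matching against ground
# truth, then recall (TPR), precision (PPV), F1 and false discovery rate.

#' Match predicted instances to ground-truth instances
#'
#' Greedy one-to-one matching by descending intersection-over-union. A truth
#' cell counts as a true positive only when matched with IoU at or above
#' `iou_complete` -- the operational proxy for "completely segmented"
#' (partially captured or over-segmented cells do not count). Unmatched
#' predictions are false positives; unmatched truths are false negatives.
#'
#' @param pred integer label matrix (or `cell_instance_set`) of predictions.
#' @param truth integer label matrix of ground-truth instances.
#' @param iou_complete IoU threshold for a complete segmentation (default 0.7).
#' @return list of class `detection_counts` with `TP`, `FP`, `FN`.
#' @export
match_instances <- function(pred, truth, iou_complete = 0.7) {
  if (inherits(pred, "cell_instance_set")) pred <- pred$labels
  stopifnot(identical(dim(pred), dim(truth)))
  np <- as.integer(max(pred)); nt <- as.integer(max(truth))
  if (np == 0 || nt == 0) {
    return(structure(list(TP = 0L, FP = as.integer(np), FN = as.integer(nt)),
                     class = "detection_counts"))
  }
  # pairwise intersections via a joint contingency table
  sel <- pred > 0 & truth > 0
  inter <- matrix(0L, np, nt)
  if (any(sel)) {
    joint <- table(factor(pred[sel], levels = seq_len(np)),
                   factor(truth[sel], levels = seq_len(nt)))
    inter <- matrix(as.integer(joint), np, nt)
  }
  area_p <- tabulate(pred[pred > 0], nbins = np)
  area_t <- tabulate(truth[truth > 0], nbins = nt)
  iou <- inter / (outer(area_p, area_t, `+`) - inter)
  cand <- which(iou >= iou_complete, arr.ind = TRUE)
  cand <- cand[order(-iou[cand]), , drop = FALSE]
  used_p <- logical(np); used_t <- logical(nt)
  tp <- 0L
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, 1]; t <- cand[i, 2]
    if (!used_p[p] && !used_t[t]) {
      used_p[p] <- used_t[t] <- TRUE
      tp <- tp + 1L
    }
  }
  structure(list(TP = tp, FP = np - tp, FN = nt - tp),
            class = "detection_counts")
}

#' Pool detection counts over several images
#'
#' Micro-averaging: counts are summed across images and the metrics are then
#' computed once on the totals.
#'
#' @param ... `detection_counts` objects (or a single list of them).
#' @return pooled `detection_counts`.
#' @export
pool_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "detection_counts")) xs <- xs[[1]]
  grab <- function(f) sum(vapply(xs, function(x) as.integer(x[[f]]),
                                 integer(1)))
  structure(list(TP = grab("TP"), FP = grab("FP"), FN = grab("FN")),
            class = "detection_counts")
}

#' Detection metrics from TP/FP/FN counts
#'
#' `TPR = TP / (TP + FN)`, `PPV = TP / (TP + FP)`,
#' `F1 = 2 PPV TPR / (PPV + TPR)` (the Dice coefficient on detections), and
#' `FDR = FP / (TP + FP) = 100% - PPV`. Reported as percentages rounded to
#' two decimals; a metric whose denominator is zero is reported as `NA`.
#'
#' @param counts a `detection_counts` (or list with TP, FP, FN).
#' @return list of class `metric_report` with `TPR`, `PPV`, `F1`, `FDR` (%).
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  if (TP + FP + FN == 0) {
    warning("all counts are zero; empty report")
    return(structure(list(TPR = NA_real_, PPV = NA_real_, F1 = NA_real_,
                          FDR = NA_real_), class = "metric_report"))
  }
  tpr <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  ppv <- if (TP + FP > 0) 100 * TP / (TP + FP) else NA_real_
  fdr <- if (TP + FP > 0) 100 - ppv else NA_real_
  f1 <- f1_score(ppv, tpr)
  structure(list(TPR = round(tpr, 2), PPV = round(ppv, 2),
                 F1 = round(f1, 2), FDR = round(fdr, 2)),
            class = "metric_report")
}

#' Harmonic mean of precision and recall (percent scale)
#'
#' @param precision,recall percentages.
#' @return F1 score in percent (unrounded).
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || precision + recall == 0)
    return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("TPR (recall):    %6.2f %%\n", x$TPR))
  cat(sprintf("PPV (precision): %6.2f %%\n", x$PPV))
  cat(sprintf("F1-score:        %6.2f %%\n", x$F1))
  cat(sprintf("FDR:             %6.2f %%\n", x$FDR))
  invisible(x)
}

#' Write a metric report (with method column) as CSV
#'
#' @param reports named list of `metric_report`s (names = method labels).
#' @param path file path.
#' @export
write_metric_table <- function(reports, path) {
  df <- do.call(rbind, lapply(names(reports), function(m) {
    r <- reports[[m]]
    data.frame(method = m, TPR = r$TPR, PPV = r$PPV, FDR = r$FDR, F1 = r$F1)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
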