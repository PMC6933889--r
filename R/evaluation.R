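#' ROC and precision-recall curves by threshold sweep
#'
#' Standard sweep over the distinct scores (descending); ROC AUC by the
#' trapezoidal rule.
#'
#' @param y_true Logical (or 0/1) vector: is the positive class.
#' @param y_scores Numeric scores, higher = more positive.
#' @return list with `roc_points` (`threshold`, `fpr`, `tpr`), `pr_points`
#'   (`threshold`, `recall`, `precision`) and `auc`; `NULL` fields when
#'   `y_true` has a single class.
#' @export
curves <- function(y_true, y_scores) {
  y <- as.logical(y_true)
  P <- sum(y); N <- sum(!y)
  if (P == 0L || N == 0L)
    return(list(roc_points = NULL, pr_points = NULL, auc = NA_real_))
  ord <- order(y_scores, decreasing = TRUE)
  ys <- y[ord]; sc <- y_scores[ord]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  last <- c(sc[-1L] != sc[-length(sc)], TRUE)  # last index of each score
  thr <- sc[last]; tp <- tp[last]; fp <- fp[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  roc <- data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr)
  prec <- tp / (tp + fp)
  pr <- data.frame(threshold = thr, recall = tp / P, precision = prec)
  list(roc_points = roc, pr_points = pr, auc = auc)
}

#' Classification metrics for the 3-class model
#'
#' Overall accuracy at argmax plus, for each positive class (donor and
#' acceptor), one-vs-rest recall `TP/(TP+FN)`, precision `TP/(TP+FP)`, the
#' F1 score (harmonic mean of the two), and the AUC of the one-vs-rest score
#' sweep with ROC and precision-recall points. A class absent from `y_true`
#' gets `NA` metrics.
#'
#' @param y_true Character vector of labels.
#' @param y_prob Probability matrix with columns named by label.
#' @return list of class `classification_report`: `accuracy`, `per_class`
#'   (data.frame), and `curves` (per-class list).
#' @export
classification_metrics <- function(y_true, y_prob) {
  stopifnot(nrow(y_prob) == length(y_true), !is.null(colnames(y_prob)))
  pred <- colnames(y_prob)[max.col(y_prob, ties.method = "first")]
  acc <- mean(pred == y_true)
  classes <- intersect(c("donor", "acceptor"), colnames(y_prob))
  rows <- list(); cv <- list()
  for (cls in classes) {
    tp <- sum(pred == cls & y_true == cls)
    fp <- sum(pred == cls & y_true != cls)
    fn <- sum(pred != cls & y_true == cls)
    if (sum(y_true == cls) == 0L) {
      rows[[cls]] <- data.frame(class = cls, auc = NA_real_,
                                recall = NA_real_, precision = NA_real_,
                                f1 = NA_real_)
      cv[[cls]] <- list(roc_points = NULL, pr_points = NULL, auc = NA_real_)
      next
    }
    recall <- tp / (tp + fn)
    precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(precision) && recall > 0 && precision > 0)
      1 / ((1 / recall + 1 / precision) / 2) else NA_real_
    cc <- curves(y_true == cls, y_prob[, cls])
    rows[[cls]] <- data.frame(class = cls, auc = cc$auc, recall = recall,
                              precision = precision, f1 = f1)
    cv[[cls]] <- cc
  }
  structure(list(accuracy = acc,
                 per_class = do.call(rbind, c(rows,
                                              make.row.names = FALSE)),
                 curves = cv),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("accuracy:", round(x$accuracy, 4), "\n")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' False-positive count at a recall target
#'
#' Sweeps the score threshold from high to low per site type; at each
#' threshold, recall is the fraction of true sites matched by a call of the
#' same type within `tolerance` nucleotides. The report gives the FP count
#' at the highest threshold whose recall reaches `recall_target`;
#' `attainable = FALSE` (FP count `NA`) when even threshold 0 misses it.
#' The combined count is the sum of per-type FP counts, each at its own
#' threshold.
#'
#' @param calls Calls data.frame from [scan_sequence()].
#' @param true_sites Site data.frame.
#' @param recall_target Target recall in (0, 1].
#' @param tolerance Match tolerance in nucleotides (default 0 =
#'   position-exact).
#' @return list of class `localization_report`: `per_type` data.frame
#'   (`site_type`, `recall_target`, `achieved_recall`, `fp_count`,
#'   `threshold`, `attainable`) and `combined_fp`.
#' @export
fp_at_recall <- function(calls, true_sites, recall_target,
                         tolerance = 0L) {
  if (recall_target <= 0 || recall_target > 1)
    stop("parameter error: recall_target must be in (0, 1]")
  rows <- list()
  for (ty in c("donor", "acceptor")) {
    truth <- true_sites[true_sites$site_type == ty, , drop = FALSE]
    cl <- calls[calls$site_type == ty, , drop = FALSE]
    if (nrow(truth) == 0L) {
      rows[[ty]] <- data.frame(site_type = ty,
                               recall_target = recall_target,
                               achieved_recall = NA_real_,
                               fp_count = NA_integer_,
                               threshold = NA_real_, attainable = NA)
      next
    }
    m <- .match_calls(cl, truth, tolerance)
    best <- NULL
    for (thr in sort(unique(cl$score), decreasing = TRUE)) {
      keep <- cl$score >= thr
      mt <- .match_calls(cl[keep, , drop = FALSE], truth, tolerance)
      rec <- mean(mt$site_matched)
      if (rec >= recall_target) {
        best <- list(threshold = thr, recall = rec,
                     fp = sum(!mt$call_matched))
        break
      }
    }
    rows[[ty]] <- if (is.null(best)) {
      full <- .match_calls(cl, truth, tolerance)
      data.frame(site_type = ty, recall_target = recall_target,
                 achieved_recall = mean(full$site_matched),
                 fp_count = NA_integer_, threshold = NA_real_,
                 attainable = FALSE)
    } else {
      data.frame(site_type = ty, recall_target = recall_target,
                 achieved_recall = best$recall,
                 fp_count = as.integer(best$fp), threshold = best$threshold,
                 attainable = TRUE)
    }
  }
  per_type <- do.call(rbind, c(rows, make.row.names = FALSE))
  combined <- if (all(per_type$attainable %in% TRUE))
    sum(per_type$fp_count) else NA_integer_
  structure(list(per_type = per_type, combined_fp = combined),
            class = "localization_report")
}

#' @export
print.localization_report <- function(x, ...) {
  print(x$per_type, row.names = FALSE)
  cat("combined FP:", x$combined_fp, "\n")
  invisible(x)
}

#' Write a classification or localization report as JSON
#' @param report Report object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  x$curves <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}
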