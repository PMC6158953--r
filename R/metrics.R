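#' Pixel-level confusion counts between a segmentation and ground truth
#'
#' TP: foreground in both; TN: background in both; FP: foreground in the
#' segmentation but background in the gold standard; FN: background in
#' the segmentation but foreground in the gold standard.
#'
#' @param pred predicted [binary_mask()].
#' @param truth ground-truth [binary_mask()], same shape.
#' @return A `confusion_counts` list with integers `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(pred, truth) {
  pred <- as_binary_mask(pred)
  truth <- as_binary_mask(truth)
  check_same_shape(pred, truth, "prediction and truth")
  p <- unclass(pred) == 1L
  g <- unclass(truth) == 1L
  structure(list(TP = sum(p & g), TN = sum(!p & !g),
                 FP = sum(p & !g), FN = sum(!p & g)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP %d  TN %d  FP %d  FN %d>\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Accuracy index, precision, recall and F1 from confusion counts
#'
#' AI = (TP+TN)/(TP+TN+FP+FN); precision = TP/(TP+FP);
#' recall = TP/(TP+FN); F1 = 2 * precision * recall /
#' (precision + recall). A zero denominator in precision or recall (and
#' hence F1 when both are zero) yields 0 with a warning rather than an
#' error, so batch evaluation never aborts.
#'
#' @param counts a `confusion_counts` object or a list with fields
#'   `TP`, `TN`, `FP`, `FN`.
#' @return A `metrics_report` list with `ai`, `precision`, `recall`,
#'   `f1`, all in `[0, 1]`.
#' @examples
#' metrics_report(list(TP = 340122, TN = 977925, FP = 13132, FN = 51947))
#' @export
metrics_report <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total <= 0) stop("all confusion counts are zero", call. = FALSE)
  ai <- (TP + TN) / total
  precision <- if (TP + FP > 0) TP / (TP + FP) else {
    warning("no predicted foreground: precision defined as 0"); 0
  }
  recall <- if (TP + FN > 0) TP / (TP + FN) else {
    warning("no true foreground: recall defined as 0"); 0
  }
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(ai = ai, precision = precision, recall = recall, f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics: AI %.4f  precision %.4f  recall %.4f  F1 %.4f>\n",
              x$ai, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Aggregate per-image confusion counts
#'
#' Two dialects: `"pooled"` sums counts over images and applies the
#' metric formulas once; `"per-image"` computes each image's metrics and
#' returns their mean and standard deviation.
#'
#' @param counts_list list of `confusion_counts`.
#' @param dialect `"pooled"` or `"per-image"`.
#' @return For `"pooled"` a `metrics_report`; for `"per-image"` a list
#'   with `mean` (a `metrics_report` of column means) and `sd` (named
#'   numeric).
#' @export
aggregate_metrics <- function(counts_list,
                              dialect = c("pooled", "per-image")) {
  dialect <- match.arg(dialect)
  if (dialect == "pooled") {
    tot <- list(TP = sum(vapply(counts_list, `[[`, 0, "TP")),
                TN = sum(vapply(counts_list, `[[`, 0, "TN")),
                FP = sum(vapply(counts_list, `[[`, 0, "FP")),
                FN = sum(vapply(counts_list, `[[`, 0, "FN")))
    metrics_report(tot)
  } else {
    reps <- lapply(counts_list, metrics_report)
    tab <- sapply(reps, function(r) unlist(r[c("ai", "precision",
                                               "recall", "f1")]))
    means <- rowMeans(tab)
    list(mean = structure(as.list(means), class = "metrics_report"),
         sd = apply(tab, 1, stats::sd))
  }
}

#' ROC operating points from a lambda sweep
#'
#' The decision variable swept to trace the ROC curve is the graph-cut
#' parameter lambda: each value yields one segmentation, hence one
#' (FPR, TPR) point. Points are augmented with (0,0) and (1,1) and sorted
#' by FPR (then TPR).
#'
#' @inheritParams segment
#' @param truth ground-truth [binary_mask()].
#' @param lambda_grid positive lambda values to sweep (non-empty).
#' @return Data frame with columns `lambda` (NA for the anchor points),
#'   `fpr`, `tpr`.
#' @export
roc_points <- function(image, seeds, mode = c("static", "adaptive"),
                       truth, lambda_grid, ...) {
  mode <- match.arg(mode)
  if (length(lambda_grid) == 0) stop("lambda grid is empty", call. = FALSE)
  truth <- as_binary_mask(truth)
  pts <- lapply(lambda_grid, function(l) {
    res <- segment(image, seeds, mode = mode, lambda1 = l, ...)
    cc <- confusion(res$mask, truth)
    data.frame(lambda = l,
               fpr = if (cc$FP + cc$TN > 0) cc$FP / (cc$FP + cc$TN) else 0,
               tpr = if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else 0)
  })
  out <- rbind(data.frame(lambda = NA, fpr = 0, tpr = 0),
               do.call(rbind, pts),
               data.frame(lambda = NA, fpr = 1, tpr = 1))
  out[order(out$fpr, out$tpr), , drop = FALSE]
}

#' Area under an ROC curve by the trapezoidal rule
#'
#' @param points data frame with `fpr` and `tpr` columns (as from
#'   [roc_points()]); need not be sorted or anchored.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1)))  # 1
#' @export
auc <- function(points) {
  if (nrow(points) == 0) stop("no ROC points", call. = FALSE)
  fpr <- c(0, points$fpr, 1)
  tpr <- c(0, points$tpr, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Welch two-sample t-test on per-image F1 scores
#'
#' t = (M2 - M1) / sqrt(SD2^2/N + SD1^2/N) with M, SD the group means and
#' standard deviations and N the (equal) group size; two-tailed p-value
#' from the t distribution with Welch-Satterthwaite degrees of freedom.
#' A difference is called significant when p < 0.05. Identical samples
#' give t = 0, p = 1.
#'
#' @param f1_a,f1_b numeric vectors of per-image F1 scores, equal length
#'   `N >= 2`.
#' @return A `t_test_result` list: `t`, `p`, `df`, `n`, `significant`.
#' @export
t_test_f1 <- function(f1_a, f1_b) {
  n <- length(f1_a)
  if (length(f1_b) != n) stop("groups must have equal size", call. = FALSE)
  if (n < 2) stop("need at least 2 images per group", call. = FALSE)
  m1 <- mean(f1_a); m2 <- mean(f1_b)
  v1 <- stats::var(f1_a); v2 <- stats::var(f1_b)
  se2 <- v1 / n + v2 / n
  if (se2 == 0) {
    if (m1 == m2) {
      t <- 0; p <- 1; df <- n - 1
    } else stop("zero variance with unequal means: degenerate test",
                call. = FALSE)
  } else {
    t <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n)^2 / (n - 1) + (v2 / n)^2 / (n - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t = t, p = p, df = df, n = n, significant = p < 0.05),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t-test: t %.4f, df %.2f, p %.4g, %ssignificant>\n",
              x$t, x$df, x$p, if (x$significant) "" else "not "))
  invisible(x)
}

#' Write a metrics report as JSON or CSV
#'
#' @param report a `metrics_report`.
#' @param path output path; `.json` or `.csv` by extension.
#' @export
write_metrics <- function(report, path) {
  vals <- report[c("ai", "precision", "recall", "f1")]
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    write.csv(as.data.frame(vals), path, row.names = FALSE)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
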