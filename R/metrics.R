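# Confusion-count bookkeeping and the full two-class evaluation panel:
# per-class precision/recall/F1, accuracy, balanced accuracy, ROC and PR
# curves with areas, and the prevalence baseline for random prediction.

#' Two-class confusion counts
#'
#' The four counts of the pooled two-class confusion matrix:
#' `tp_co`/`fn_co` are competition examples classified correctly /
#' misclassified as cross-feeding, `fn_cf`/`tp_cf` are cross-feeding
#' examples misclassified as competition / classified correctly.
#'
#' @param tp_co,fn_co,fn_cf,tp_cf Non-negative integers.
#' @return An object of class `confusion_counts`.
#' @export
#' @examples
#' confusion_counts(401, 145, 130, 1976)
confusion_counts <- function(tp_co, fn_co, fn_cf, tp_cf) {
  v <- c(tp_co = tp_co, fn_co = fn_co, fn_cf = fn_cf, tp_cf = tp_cf)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  v <- as.list(setNames(as.integer(v), names(v)))
  structure(v, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> tp_co=", x$tp_co, " fn_co=", x$fn_co,
      " fn_cf=", x$fn_cf, " tp_cf=", x$tp_cf, "\n", sep = "")
  invisible(x)
}

#' Confusion counts from paired truth/prediction labels
#'
#' @param truth,predicted Character vectors of `"cross_feeding"` /
#'   `"competition"` labels.
#' @return A [confusion_counts()].
#' @export
counts_from_predictions <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% .LABELS), all(predicted %in% .LABELS))
  confusion_counts(
    tp_co = sum(truth == .CO & predicted == .CO),
    fn_co = sum(truth == .CO & predicted == .CF),
    fn_cf = sum(truth == .CF & predicted == .CO),
    tp_cf = sum(truth == .CF & predicted == .CF)
  )
}

# Display rounding: two decimals, half-up, trailing zeros trimmed
# ("0.896" prints as "0.9"). The tiny offset guards against binary
# representation of values like 0.755.
format_metric <- function(x) {
  r <- floor(x * 100 + 0.5 + 1e-9) / 100
  sub("\\.?0+$", "", sprintf("%.2f", r))
}

#' Scalar metric panel from confusion counts
#'
#' Computes per-class precision, recall and F1 with each class in turn as
#' the target, plus global accuracy and balanced accuracy (mean of the two
#' recalls), from pooled confusion counts. Zero-denominator metrics are
#' defined as 0 and listed in `zero_denominator` so reports stay
#' machine-readable.
#'
#' @param counts A [confusion_counts()].
#' @return An object of class `metric_panel`: numeric fields at full
#'   precision (`precision`, `recall`, `f1` — each named by class —
#'   `accuracy`, `balanced_accuracy`), `display` strings rounded to two
#'   decimals half-up with trailing zeros trimmed, and `zero_denominator`.
#' @export
#' @examples
#' panel_from_counts(confusion_counts(401, 145, 130, 1976))
panel_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp_co + counts$fn_co + counts$fn_cf + counts$tp_cf
  if (n == 0L) stop("all confusion counts are zero", call. = FALSE)
  flags <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      flags <<- c(flags, what)
      return(0)
    }
    num / den
  }
  p_co <- safe_div(counts$tp_co, counts$tp_co + counts$fn_cf, "precision.competition")
  r_co <- safe_div(counts$tp_co, counts$tp_co + counts$fn_co, "recall.competition")
  p_cf <- safe_div(counts$tp_cf, counts$tp_cf + counts$fn_co, "precision.cross_feeding")
  r_cf <- safe_div(counts$tp_cf, counts$tp_cf + counts$fn_cf, "recall.cross_feeding")
  f_co <- safe_div(2 * p_co * r_co, p_co + r_co, "f1.competition")
  f_cf <- safe_div(2 * p_cf * r_cf, p_cf + r_cf, "f1.cross_feeding")
  acc <- (counts$tp_co + counts$tp_cf) / n
  bacc <- (r_co + r_cf) / 2
  panel <- list(
    precision = c(competition = p_co, cross_feeding = p_cf),
    recall = c(competition = r_co, cross_feeding = r_cf),
    f1 = c(competition = f_co, cross_feeding = f_cf),
    accuracy = acc,
    balanced_accuracy = bacc
  )
  panel$display <- lapply(panel, function(v) {
    out <- vapply(v, format_metric, character(1))
    if (is.null(names(v))) unname(out) else out
  })
  panel$zero_denominator <- flags
  structure(panel, class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, ...) {
  d <- x$display
  cat("<metric_panel>\n",
      "  competition:   P=", d$precision[["competition"]],
      " R=", d$recall[["competition"]], " F1=", d$f1[["competition"]], "\n",
      "  cross_feeding: P=", d$precision[["cross_feeding"]],
      " R=", d$recall[["cross_feeding"]], " F1=", d$f1[["cross_feeding"]],
      "\n",
      "  accuracy=", d$accuracy, " balanced_accuracy=",
      d$balanced_accuracy, "\n", sep = "")
  if (length(x$zero_denominator) > 0L) {
    cat("  zero-denominator metrics: ",
        paste(x$zero_denominator, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Precision of a label-agnostic random predictor
#'
#' A predictor that assigns labels independently of the input attains, for
#' each class, a precision equal to that class's prevalence. Under the
#' curated interaction set (546 competition, 2,106 cross-feeding oriented
#' examples) this floor is 0.21 for competition and 0.79 for cross-feeding.
#'
#' @param class_counts Named numeric vector of per-class example counts
#'   (names `cross_feeding`, `competition`), e.g. a `pair_dataset`'s
#'   `class_counts`.
#' @return Named numeric vector of per-class baseline precisions.
#' @export
random_baseline_precision <- function(class_counts) {
  total <- sum(class_counts)
  if (total <= 0) stop("class counts sum to zero", call. = FALSE)
  class_counts / total
}

# Shared threshold sweep: per-class score, descending unique thresholds,
# cumulative true/false positives per threshold group.
.sweep <- function(scores, truth, target) {
  stopifnot(all(truth %in% .LABELS), target %in% .LABELS,
            length(scores) == length(truth))
  s <- if (target == .CF) scores else 1 - scores
  pos <- truth == target
  if (all(pos) || !any(pos)) {
    stop("both classes must be present to sweep thresholds", call. = FALSE)
  }
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  pos <- pos[ord]
  last <- cumsum(rle(s)$lengths)  # last index of each tied score group
  tp <- cumsum(pos)[last]
  fp <- cumsum(!pos)[last]
  list(tp = tp, fp = fp, n_pos = sum(pos), n_neg = sum(!pos),
       thresholds = s[last])
}

#' ROC curve and area for one target class
#'
#' The target-class score is the cross-feeding score itself when the target
#' is cross-feeding and its complement for competition. The curve sweeps
#' every unique score as a threshold; the area is computed by the
#' trapezoidal rule and equals the normalized Mann-Whitney statistic.
#'
#' @param scores Numeric cross-feeding scores in `[0, 1]`.
#' @param truth Character vector of true labels.
#' @param target Target class (`"competition"` or `"cross_feeding"`).
#' @return An object of class `curve_result`: `target`, `points` (data
#'   frame `fpr`, `tpr`), `auc`.
#' @export
roc_curve_and_auc <- function(scores, truth, target = .CO) {
  sw <- .sweep(scores, truth, target)
  tpr <- c(0, sw$tp / sw$n_pos)
  fpr <- c(0, sw$fp / sw$n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(target = target,
                 points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "curve_result")
}

#' Precision-recall curve and area for one target class
#'
#' Precision and recall at every unique score threshold; the area follows
#' the step-wise average-precision convention, `sum((R_i - R_{i-1}) * P_i)`
#' — linear PR interpolation is known to be optimistic and is deliberately
#' not used.
#'
#' @inheritParams roc_curve_and_auc
#' @return An object of class `curve_result`: `target`, `points` (data
#'   frame `recall`, `precision`), `auc`.
#' @export
pr_curve_and_auc <- function(scores, truth, target = .CO) {
  sw <- .sweep(scores, truth, target)
  precision <- sw$tp / (sw$tp + sw$fp)
  recall <- sw$tp / sw$n_pos
  auc <- sum(diff(c(0, recall)) * precision)
  structure(list(target = target,
                 points = data.frame(recall = recall,
                                     precision = precision),
                 auc = auc),
            class = "curve_result")
}

#' @export
print.curve_result <- function(x, ...) {
  kind <- if ("fpr" %in% names(x$points)) "ROC" else "PR"
  cat("<curve_result> ", kind, " target=", x$target,
      " area=", format_metric(x$auc), " (", nrow(x$points), " points)\n",
      sep = "")
  invisible(x)
}

#' Full JSON-ready evaluation report for a cross-validation result
#'
#' @param cv A `cv_result` from [cross_validate()].
#' @return A list with the model family, pooled counts, metric panel
#'   (full precision and display strings) and ROC/PR areas for both target
#'   classes; pass to [write_metric_report()] to serialize.
#' @export
evaluation_report <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  p <- cv$predictions
  list(
    model = cv$spec$family,
    counts = unclass(cv$counts),
    panel = unclass(cv$panel),
    roc = list(
      competition = roc_curve_and_auc(p$score, p$truth, .CO)$auc,
      cross_feeding = roc_curve_and_auc(p$score, p$truth, .CF)$auc),
    pr = list(
      competition = pr_curve_and_auc(p$score, p$truth, .CO)$auc,
      cross_feeding = pr_curve_and_auc(p$score, p$truth, .CF)$auc)
  )
}
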