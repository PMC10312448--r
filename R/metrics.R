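#' Confusion matrix
#'
#' Cross-tabulates predicted against observed class labels. Rows are
#' predicted classes, columns observed classes; classes are sorted
#' lexicographically and include classes present in only one of the two
#' vectors.
#'
#' @param predicted,observed Equal-length label vectors.
#' @return Object of class `confusion_matrix`: list with sorted `classes`
#'   and the `C x C` integer `counts` matrix.
#' @export
confusion_matrix <- function(predicted, observed) {
  predicted <- as.character(predicted)
  observed <- as.character(observed)
  if (length(predicted) != length(observed))
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  if (length(predicted) < 1L) stop("empty label vectors", call. = FALSE)
  classes <- sort(unique(c(predicted, observed)))
  counts <- table(factor(predicted, levels = classes),
                  factor(observed, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(predicted = classes, observed = classes))
  structure(list(classes = classes, counts = counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = predicted, cols = observed):\n")
  print(x$counts)
  invisible(x)
}

# one-vs-rest collapse of class `cl`: returns tp, fp, fn, tn
collapse_ovr <- function(cm, cl) {
  i <- match(cl, cm$classes)
  tp <- cm$counts[i, i]
  fp <- sum(cm$counts[i, -i])
  fn <- sum(cm$counts[-i, i])
  tn <- sum(cm$counts[-i, -i])
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# a ratio that is NA (undefined) rather than NaN/0 on a zero denominator
safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

# the full per-class metric slice from one-vs-rest counts
class_metric_slice <- function(tp, fp, fn, tn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn); tn <- unname(tn)
  total <- tp + fp + fn + tn
  precision <- safe_ratio(tp, tp + fp)
  sensitivity <- safe_ratio(tp, tp + fn)
  specificity <- safe_ratio(tn, tn + fp)
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            (precision + sensitivity) == 0) NA_real_
        else 2 * precision * sensitivity / (precision + sensitivity)
  bal_acc <- if (is.na(sensitivity) || is.na(specificity)) NA_real_
             else (sensitivity + specificity) / 2
  c(precision = precision,
    sensitivity = sensitivity,
    specificity = specificity,
    F1 = f1,
    balanced_accuracy = bal_acc,
    prevalence = safe_ratio(tp + fn, total),
    detection_rate = safe_ratio(tp, total),
    detection_prevalence = safe_ratio(tp + fp, total),
    PPV = precision,
    NPV = safe_ratio(tn, tn + fn))
}

#' Binary classification metrics
#'
#' Evaluates the standard two-class metric suite for a designated positive
#' class: precision (= PPV), sensitivity, specificity, F1, balanced
#' accuracy, prevalence, detection rate, detection prevalence, NPV, plus
#' overall accuracy and Cohen's kappa. Ratios with zero denominators are
#' reported as `NA` (undefined), never coerced to 0.
#'
#' @param cm A two-class [confusion_matrix()].
#' @param positive The positive class label; defaults to the first class
#'   in sorted order.
#' @return Named list of metric values.
#' @export
binary_metrics <- function(cm, positive = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (length(cm$classes) != 2L)
    stop("binary_metrics requires exactly 2 classes; use multiclass_metrics",
         call. = FALSE)
  if (is.null(positive)) positive <- cm$classes[1L]
  if (!positive %in% cm$classes)
    stop("unknown positive class '", positive, "'", call. = FALSE)
  cnt <- collapse_ovr(cm, positive)
  out <- as.list(class_metric_slice(cnt["tp"], cnt["fp"], cnt["fn"], cnt["tn"]))
  out$accuracy <- sum(diag(cm$counts)) / sum(cm$counts)
  out$kappa <- cohen_kappa(cm)
  out$positive <- positive
  out
}

#' Multi-class classification metrics
#'
#' Per-class metrics via one-vs-rest collapse of the confusion matrix,
#' aggregated as unweighted macro means over the classes for which a
#' metric is defined (micro averaging of the count-based metrics is
#' available via `average = "micro"`). Overall accuracy is
#' trace / total and kappa is chance-corrected agreement.
#'
#' @param cm A [confusion_matrix()] with `C >= 2` classes.
#' @param average `"macro"` (default) or `"micro"`.
#' @return Object of class `metrics_report`: list with `per_class`
#'   (data frame, one row per class), `macro` (named vector), `accuracy`,
#'   `kappa`, `average`.
#' @export
multiclass_metrics <- function(cm, average = c("macro", "micro")) {
  stopifnot(inherits(cm, "confusion_matrix"))
  average <- match.arg(average)
  if (sum(cm$counts) == 0L) stop("empty confusion matrix", call. = FALSE)
  if (length(cm$classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  slices <- t(vapply(cm$classes, function(cl) {
    cnt <- collapse_ovr(cm, cl)
    class_metric_slice(cnt["tp"], cnt["fp"], cnt["fn"], cnt["tn"])
  }, numeric(10)))
  per_class <- data.frame(class = cm$classes, slices, row.names = NULL)
  if (average == "macro") {
    agg <- colMeans(slices, na.rm = TRUE)
    agg[colSums(!is.na(slices)) == 0L] <- NA_real_
  } else {
    tot <- rowSums(vapply(cm$classes, function(cl) collapse_ovr(cm, cl),
                          numeric(4)))
    agg <- class_metric_slice(tot["tp"], tot["fp"], tot["fn"], tot["tn"])
  }
  structure(
    list(per_class = per_class, macro = agg,
         accuracy = sum(diag(cm$counts)) / sum(cm$counts),
         kappa = cohen_kappa(cm), average = average),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (%s averaging): accuracy %.4f, kappa %.4f\n",
              x$average, x$accuracy, x$kappa))
  cat(sprintf("  macro F1 %.4f, macro balanced accuracy %.4f\n",
              x$macro["F1"], x$macro["balanced_accuracy"]))
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is
#' observed agreement (trace / total) and `p_e` the expected agreement
#' from the row and column marginals. Returns 0 by convention when
#' `p_e = 1`.
#'
#' @param cm A [confusion_matrix()].
#' @return Scalar in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm$counts)
  if (total < 1L) stop("empty confusion matrix", call. = FALSE)
  p_o <- sum(diag(cm$counts)) / total
  p_e <- sum(rowSums(cm$counts) * colSums(cm$counts)) / total^2
  if (abs(1 - p_e) < 1e-15) return(0)
  (p_o - p_e) / (1 - p_e)
}

#' Relative method rank within a dataset
#'
#' Ranks methods by an error metric (ascending; ties get average ranks)
#' and maps ranks linearly onto `[-1, 1]`: the best method scores -1, the
#' worst +1. Averaging these scores across datasets gives each method's
#' mean relative rank.
#'
#' @param errors Named numeric vector of per-method error values for one
#'   dataset (length >= 2).
#' @return Named numeric vector of normalized rank scores in `[-1, 1]`.
#' @export
relative_rank <- function(errors) {
  if (length(errors) < 2L)
    stop("need at least 2 methods to rank", call. = FALSE)
  r <- rank(errors, ties.method = "average")
  out <- -1 + 2 * (r - 1) / (length(errors) - 1)
  names(out) <- names(errors)
  out
}

#' Area under the ROC curve
#'
#' Binary AUC from positive-class probabilities via the rank (Wilcoxon)
#' statistic; for more than two observed classes, the unweighted mean of
#' one-vs-rest AUCs.
#'
#' @param probs `n x C` matrix of class probabilities with class names as
#'   column names, or for binary input a vector of positive-class
#'   probabilities.
#' @param truth Observed labels.
#' @param positive Positive class for the binary case (default: first
#'   sorted class).
#' @return AUC in `[0, 1]`, or `NA` if only one class is observed.
#' @export
roc_auc <- function(probs, truth, positive = NULL) {
  truth <- as.character(truth)
  obs <- sort(unique(truth))
  if (length(obs) < 2L) return(NA_real_)
  auc1 <- function(p, is_pos) {
    n1 <- sum(is_pos); n0 <- sum(!is_pos)
    (sum(rank(p)[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  if (is.null(dim(probs))) {
    if (is.null(positive)) positive <- obs[1L]
    return(auc1(probs, truth == positive))
  }
  probs <- as.matrix(probs)
  if (length(obs) == 2L) {
    if (is.null(positive)) positive <- obs[1L]
    return(auc1(probs[, positive], truth == positive))
  }
  mean(vapply(obs, function(cl) auc1(probs[, cl], truth == cl), numeric(1)))
}

#' Multinomial log loss
#'
#' Mean negative log probability assigned to the observed class,
#' probabilities clipped to `[1e-15, 1 - 1e-15]`.
#'
#' @param probs `n x C` probability matrix with class column names.
#' @param truth Observed labels.
#' @return Non-negative scalar (lower is better).
#' @export
log_loss <- function(probs, truth) {
  probs <- as.matrix(probs)
  truth <- as.character(truth)
  p <- probs[cbind(seq_along(truth), match(truth, colnames(probs)))]
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  -mean(log(p))
}

# names of selection metrics and their direction
metric_direction <- function(metric_name) {
  if (metric_name == "log_loss") "ascending" else "descending"
}

# score one set of probabilistic predictions under a named metric.
# `truth` may contain a subset of the prob columns (e.g. out-of-bag sets
# missing a class): count-based metrics are computed on observed classes.
metric_score <- function(metric_name, truth, probs, positive = NULL) {
  truth <- as.character(truth)
  probs <- as.matrix(probs)
  pred <- colnames(probs)[max.col(probs, ties.method = "first")]
  cm <- confusion_matrix(pred, truth)
  switch(metric_name,
    ROC_AUC = roc_auc(probs, truth, positive),
    Kappa = cohen_kappa(cm),
    log_loss = log_loss(probs, truth),
    accuracy = sum(diag(cm$counts)) / sum(cm$counts),
    balanced_accuracy = {
      obs <- sort(unique(truth))
      vals <- vapply(obs, function(cl) {
        cnt <- collapse_ovr(cm, cl)
        slice <- class_metric_slice(cnt["tp"], cnt["fp"], cnt["fn"], cnt["tn"])
        slice[["balanced_accuracy"]]
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    },
    F1 = {
      if (length(cm$classes) == 2L && !is.null(positive)) {
        binary_metrics(cm, positive)$F1
      } else {
        obs <- sort(unique(truth))
        vals <- vapply(obs, function(cl) {
          cnt <- collapse_ovr(cm, cl)
          class_metric_slice(cnt["tp"], cnt["fp"], cnt["fn"], cnt["tn"])[["F1"]]
        }, numeric(1))
        mean(vals, na.rm = TRUE)
      }
    },
    stop("unknown metric '", metric_name, "'", call. = FALSE)
  )
}
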