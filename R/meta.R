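#' Proportion of shape variation explained by class
#'
#' Multivariate R-squared of a linear model of the flattened shape
#' coordinates on class membership: `1 - SS_within / SS_total`, where
#' `SS_total` sums squared distances of specimens to the grand mean and
#' `SS_within` squared distances to the class means. Optionally a
#' permutation p-value is computed by recomputing R-squared under label
#' permutations (a residual-randomization analogue; the point estimate
#' itself is deterministic).
#'
#' @param flat_shapes `n x d` numeric matrix.
#' @param labels Class labels; >= 2 classes, each with >= 2 members.
#' @param n_perm Number of label permutations for the optional p-value
#'   (0 = skip).
#' @param seed Seed for the permutations.
#' @return R-squared in `[0, 1]`; if `n_perm > 0`, with attribute
#'   `"p_value"`.
#' @export
class_r2 <- function(flat_shapes, labels, n_perm = 0L, seed = 1L) {
  x <- as.matrix(flat_shapes)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(tab < 2L))
    stop("class(es) with a single member: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  r2_of <- function(lab) {
    grand <- colMeans(x)
    ss_t <- sum(sweep(x, 2L, grand)^2)
    ss_w <- 0
    for (cl in unique(lab)) {
      xi <- x[lab == cl, , drop = FALSE]
      ss_w <- ss_w + sum(sweep(xi, 2L, colMeans(xi))^2)
    }
    if (ss_t == 0) return(0)
    1 - ss_w / ss_t
  }
  r2 <- r2_of(labels)
  if (n_perm > 0L) {
    set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(i) r2_of(sample(labels)),
                   numeric(1))
    attr(r2, "p_value") <- (1 + sum(perm >= r2)) / (n_perm + 1)
  }
  r2
}

#' Mean pairwise distance between class covariance matrices
#'
#' Frobenius (Euclidean) norm of the difference between the sample
#' covariance matrices (denominator `n_c - 1`) of every unordered pair of
#' classes, averaged over the `C (C - 1) / 2` pairs.
#'
#' @param flat_shapes `n x d` numeric matrix.
#' @param labels Class labels; every class needs >= 3 members.
#' @return Non-negative scalar.
#' @export
mean_class_cov_distance <- function(flat_shapes, labels) {
  x <- as.matrix(flat_shapes)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(tab < 3L))
    stop("class(es) too small for covariance estimation: ",
         paste(names(tab)[tab < 3L], collapse = ", "), call. = FALSE)
  classes <- sort(names(tab))
  covs <- lapply(classes, function(cl) stats::cov(x[labels == cl, , drop = FALSE]))
  pairs <- utils::combn(length(classes), 2L)
  mean(apply(pairs, 2L, function(pr)
    sqrt(sum((covs[[pr[1L]]] - covs[[pr[2L]]])^2))))
}

#' Mean pairwise Procrustes distance between class mean shapes
#'
#' Computes each class's mean shape from the aligned coordinates and
#' averages the Procrustes distances over every unordered pair of
#' classes.
#'
#' @param aligned An `aligned_shapes` object.
#' @param labels Class labels (defaults to those carried on `aligned`).
#' @return Non-negative scalar.
#' @export
mean_class_shape_distance <- function(aligned, labels = aligned$labels) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  means <- lapply(classes, function(cl) mean_shape(aligned, labels == cl))
  pairs <- utils::combn(length(classes), 2L)
  mean(apply(pairs, 2L, function(pr)
    procrustes_distance(means[[pr[1L]]], means[[pr[2L]]])))
}

#' Between- over within-class variance ratio
#'
#' Quotient of the traces of the between-class and within-class
#' covariance matrices, both on the `n - 1` denominator so that
#' `trace(B) + trace(W)` equals the trace of the total covariance
#' exactly.
#'
#' @param flat_shapes `n x d` numeric matrix.
#' @param labels Class labels; >= 2 classes, each with >= 2 members.
#' @return Non-negative scalar (`trace(B) / trace(W)`).
#' @export
variance_ratio <- function(flat_shapes, labels) {
  x <- as.matrix(flat_shapes)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(tab < 2L))
    stop("class(es) with a single member: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  n <- nrow(x)
  grand <- colMeans(x)
  tr_b <- 0; tr_w <- 0
  for (cl in names(tab)) {
    xi <- x[labels == cl, , drop = FALSE]
    mu <- colMeans(xi)
    tr_b <- tr_b + nrow(xi) * sum((mu - grand)^2)
    tr_w <- tr_w + sum(sweep(xi, 2L, mu)^2)
  }
  tr_b <- tr_b / (n - 1)
  tr_w <- tr_w / (n - 1)
  if (tr_w == 0) stop("no within-class variation", call. = FALSE)
  tr_b / tr_w
}

#' Class balance as normalized Shannon entropy
#'
#' `H / ln(C)` where `H = -sum p_c ln p_c` over the class proportions:
#' 1 for perfectly balanced classes, approaching 0 under extreme
#' imbalance. The logarithm base cancels in the ratio.
#'
#' @param counts Named vector (or table) of positive per-class counts,
#'   `C >= 2`.
#' @return Scalar in `[0, 1]`.
#' @export
class_balance <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L)
    stop("need at least 2 classes (normalizer is ln C)", call. = FALSE)
  if (any(counts < 1)) stop("all class counts must be >= 1", call. = FALSE)
  p <- counts / sum(counts)
  -sum(p * log(p)) / log(length(counts))
}

#' All dataset-level phenotypic properties at once
#'
#' @param aligned An `aligned_shapes` object (its `flat` matrix feeds the
#'   covariance-based statistics).
#' @param labels Class labels (defaults to those carried on `aligned`).
#' @return A one-row data frame: `class_r2`, `mean_cov_distance`,
#'   `mean_shape_distance`, `variance_ratio`, `class_balance`,
#'   `sample_size`, `task` (`binary`/`multi`).
#' @export
dataset_properties <- function(aligned, labels = aligned$labels) {
  labels <- as.character(labels)
  data.frame(
    class_r2 = class_r2(aligned$flat, labels),
    mean_cov_distance = mean_class_cov_distance(aligned$flat, labels),
    mean_shape_distance = mean_class_shape_distance(aligned, labels),
    variance_ratio = variance_ratio(aligned$flat, labels),
    class_balance = class_balance(table(labels)),
    sample_size = length(labels),
    task = if (length(unique(labels)) == 2L) "binary" else "multi"
  )
}

#' Meta-regression of performance on a dataset property
#'
#' Ordinary least squares of a per-dataset performance metric (in
#' percentage points) on an intercept, a classification-task indicator
#' (binary = 0, multi = 1), and one continuous dataset property. Effects
#' are reported per `unit` of the property (conventionally 0.1 for most
#' properties, 0.01 for shape distance, 1 for sample size).
#'
#' @param performance Numeric vector of metric values (percent), one per
#'   dataset (or per method-dataset row).
#' @param property_values Numeric vector, same length.
#' @param task_flags `"binary"`/`"multi"` (or 0/1) vector, same length;
#'   both tasks must be present.
#' @param unit Per-unit scaling of the property effect (0.1, 0.01, or 1).
#' @return Object of class `meta_regression`: list with
#'   `variable_effect_per_unit`, `task_effect`, `unit`, `se` (residual
#'   standard error), `f_statistic`, `r2`, and the underlying `fit`.
#' @export
meta_regression <- function(performance, property_values, task_flags,
                            unit = 0.1) {
  if (is.character(task_flags) || is.factor(task_flags))
    task_flags <- as.integer(as.character(task_flags) == "multi")
  df <- data.frame(perf = performance, task = task_flags,
                   prop = property_values)
  if (nrow(df) < 4L) stop("need at least 4 datasets", call. = FALSE)
  if (length(unique(df$task)) < 2L)
    stop("both binary and multi-class datasets are required", call. = FALSE)
  fit <- stats::lm(perf ~ task + prop, data = df)
  if (any(is.na(coef(fit)))) stop("rank-deficient design", call. = FALSE)
  sm <- summary(fit)
  structure(
    list(variable_effect_per_unit = unname(coef(fit)["prop"]) * unit,
         task_effect = unname(coef(fit)["task"]),
         unit = unit, se = sm$sigma,
         f_statistic = unname(sm$fstatistic["value"]),
         r2 = sm$r.squared, fit = fit),
    class = "meta_regression"
  )
}

#' @export
print.meta_regression <- function(x, ...) {
  cat(sprintf(paste0("meta_regression: effect %+.3f%% per %g unit, ",
                     "task effect %+.3f%%, SE %.2f, F %.2f, R2 %.3f\n"),
              x$variable_effect_per_unit, x$unit, x$task_effect,
              x$se, x$f_statistic, x$r2))
  invisible(x)
}
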