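#' Anomaly removal by the Procrustes-distance interquartile fence
#'
#' Computes each specimen's Procrustes distance to the consensus shape and
#' flags specimens beyond `Q3 + multiplier * IQR` of the distance
#' distribution (Tukey's fence at the default multiplier of 1.5). This is
#' the classical outlier rule for superimposed landmark data; more generic
#' anomaly scores (see [isolation_scores()]) can be screened against it
#' with [anomaly_score_correlation()] but removal uses only this rule.
#'
#' If `labels` are supplied, removal never empties a class: specimens whose
#' removal would do so are retained and a warning is issued.
#'
#' The rule is idempotent when re-applied to the retained set against the
#' *same* consensus; the consensus is deliberately not recomputed here, so
#' the filter is a single pass, not a recursive trim.
#'
#' @param aligned An `aligned_shapes` object.
#' @param multiplier Non-negative fence multiplier; `Inf` disables removal.
#' @param labels Optional class labels (length n) enabling the
#'   class-protection guard.
#' @return List with `kept` and `removed` integer index vectors, the
#'   per-specimen `distances`, and the `threshold` used.
#' @export
procrustes_iqr_filter <- function(aligned, multiplier = 1.5, labels = NULL) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  n <- dim(aligned$coords)[1L]
  if (n < 4L) stop("need at least 4 specimens for quartile-based filtering",
                   call. = FALSE)
  distances <- vapply(seq_len(n), function(i)
    procrustes_distance(aligned$consensus, aligned$coords[i, , ]), numeric(1))
  if (!is.finite(multiplier)) {
    return(list(kept = seq_len(n), removed = integer(0),
                distances = distances, threshold = Inf))
  }
  qs <- stats::quantile(distances, c(0.25, 0.75), names = FALSE)
  threshold <- qs[2L] + multiplier * (qs[2L] - qs[1L])
  # absolute guard so numerically identical shapes never trip the fence
  removed <- which(distances > threshold + 1e-12)
  if (!is.null(labels) && length(removed)) {
    labels <- as.character(labels)
    for (cl in unique(labels[removed])) {
      members <- which(labels == cl)
      if (all(members %in% removed)) {
        warning("IQR filter would empty class '", cl, "'; retaining its specimens")
        removed <- setdiff(removed, members)
      }
    }
  }
  list(kept = setdiff(seq_len(n), removed), removed = removed,
       distances = distances, threshold = threshold)
}

#' Correlation between anomaly scores and Procrustes distances
#'
#' Diagnostic for any pluggable per-specimen anomaly score: its Pearson
#' correlation with the Procrustes distances to the mean shape. High
#' positive correlation indicates the generic detector agrees with the
#' morphometric convention.
#'
#' @param scores,distances Equal-length numeric vectors (n >= 3), neither
#'   constant.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
anomaly_score_correlation <- function(scores, distances) {
  if (length(scores) != length(distances))
    stop("`scores` and `distances` must have equal length", call. = FALSE)
  if (length(scores) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(scores) == 0 || stats::sd(distances) == 0)
    stop("constant input vector: correlation undefined", call. = FALSE)
  stats::cor(scores, distances)
}

#' Isolation-forest anomaly scores
#'
#' A standard isolation forest: trees are grown by uniformly random
#' axis-aligned splits on subsamples, and a specimen's score is
#' `2^(-E[h]/c(psi))` where `E[h]` is its mean path length and `c(psi)` the
#' expected path length of an unsuccessful BST search. Scores near 1 mark
#' isolates; near 0.5 and below, ordinary points. Serves as the generic
#' anomaly-score adapter for [anomaly_score_correlation()].
#'
#' @param x Numeric matrix (rows = specimens).
#' @param n_trees Number of isolation trees.
#' @param sample_size Subsample size per tree (capped at n).
#' @param seed Integer seed; scores are deterministic given it.
#' @return Numeric vector of anomaly scores in (0, 1).
#' @export
isolation_scores <- function(x, n_trees = 100L, sample_size = 256L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  psi <- min(sample_size, n)
  hlim <- ceiling(log2(max(psi, 2)))
  avg_path <- function(m) {
    ifelse(m > 2, 2 * (log(m - 1) + 0.5772156649) - 2 * (m - 1) / m,
           ifelse(m == 2, 1, 0))
  }
  grow <- function(idx, depth) {
    if (depth >= hlim || length(idx) <= 1L) {
      return(list(leaf = TRUE, size = length(idx)))
    }
    j <- sample.int(ncol(x), 1L)
    rng <- range(x[idx, j])
    if (rng[1L] == rng[2L]) return(list(leaf = TRUE, size = length(idx)))
    s <- stats::runif(1, rng[1L], rng[2L])
    left <- idx[x[idx, j] < s]
    right <- setdiff(idx, left)
    list(leaf = FALSE, var = j, split = s,
         left = grow(left, depth + 1L), right = grow(right, depth + 1L))
  }
  path_len <- function(node, row, depth) {
    if (node$leaf) return(depth + avg_path(node$size))
    if (row[node$var] < node$split) path_len(node$left, row, depth + 1L)
    else path_len(node$right, row, depth + 1L)
  }
  set.seed(seed)
  depths <- matrix(0, n, n_trees)
  for (t in seq_len(n_trees)) {
    tree <- grow(sample.int(n, psi), 0L)
    depths[, t] <- apply(x, 1L, function(r) path_len(tree, r, 0L))
  }
  2^(-rowMeans(depths) / avg_path(psi))
}

# nearest-integer rounding, halves away from zero (not banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' Stratified three-way data partition
#'
#' Two-stage blending split: per class, `round(test_fraction * n_c)`
#' specimens go to the test set, then `round(validation_fraction *
#' remaining)` of the remainder to the validation set, the rest to
#' training (rounding to nearest, halves away from zero, with a per-class
#' minimum of one specimen in test and validation). At the default
#' 0.15/0.15 fractions this realizes the 85/15 train/test split with 15%
#' of the training data reserved for validation. A `direct` scheme
#' allocating `round(f * n_c)` of each class straight to test and
#' validation (a plain 70/15/15) is also available.
#'
#' @param labels Class labels, length n; every class needs >= 3 members.
#' @param test_fraction,validation_fraction Fractions in (0, 0.5).
#' @param seed Integer seed; identical seed gives an identical partition.
#' @param scheme `"two_stage"` (default) or `"direct"`.
#' @return Object of class `partition`: list with disjoint `train_idx`,
#'   `validation_idx`, `test_idx` covering all n specimens, plus
#'   `fractions`, `seed`, `scheme`.
#' @export
stratified_split <- function(labels, test_fraction = 0.15,
                             validation_fraction = 0.15, seed = 1L,
                             scheme = c("two_stage", "direct")) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  n <- length(labels)
  if (test_fraction <= 0 || test_fraction >= 0.5 ||
      validation_fraction <= 0 || validation_fraction >= 0.5)
    stop("fractions must lie in (0, 0.5)", call. = FALSE)
  classes <- sort(unique(labels))
  counts <- table(labels)
  small <- names(counts)[counts < 3L]
  if (length(small))
    stop("class(es) with fewer than 3 members cannot be stratified: ",
         paste(small, collapse = ", "), call. = FALSE)
  test_idx <- validation_idx <- train_idx <- integer(0)
  set.seed(seed)
  for (cl in classes) {
    idx <- which(labels == cl)
    n_c <- length(idx)
    perm <- idx[sample.int(n_c)]
    if (scheme == "two_stage") {
      n_test <- max(1L, round_half_up(test_fraction * n_c))
      rem <- n_c - n_test
      n_val <- max(1L, round_half_up(validation_fraction * rem))
    } else {
      n_test <- max(1L, round_half_up(test_fraction * n_c))
      n_val <- max(1L, round_half_up(validation_fraction * n_c))
    }
    n_train <- n_c - n_test - n_val
    if (n_train < 1L)
      stop("fractions leave class '", cl, "' with an empty training set",
           call. = FALSE)
    test_idx <- c(test_idx, perm[seq_len(n_test)])
    validation_idx <- c(validation_idx, perm[n_test + seq_len(n_val)])
    train_idx <- c(train_idx, perm[(n_test + n_val + 1L):n_c])
  }
  structure(
    list(train_idx = sort(train_idx), validation_idx = sort(validation_idx),
         test_idx = sort(test_idx),
         fractions = c(test_fraction = test_fraction,
                       validation_fraction = validation_fraction),
         seed = seed, scheme = scheme),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition (%s, seed %d): train %d / validation %d / test %d\n",
              x$scheme, x$seed, length(x$train_idx),
              length(x$validation_idx), length(x$test_idx)))
  invisible(x)
}

#' Fit a PCA feature extractor on training data
#'
#' Centers on the training mean and decomposes the centered matrix by SVD
#' (covariance denominator n - 1). The smallest number of leading
#' components whose cumulative explained-variance ratio reaches
#' `variance_threshold` is retained; at a threshold of 1 every component
#' with positive variance (at most `min(n - 1, d)`) is kept.
#'
#' @param train_flat Numeric `n x d` training matrix, `n >= 3`, `d >= 2`.
#' @param variance_threshold Fraction of variance to retain, in (0, 1].
#' @return Object of class `pca_model`: `center`, `rotation` (`d x m`,
#'   orthonormal columns), `explained_variance_ratio`, `n_retained`,
#'   `variance_threshold`, and the training `scores`.
#' @export
pca_fit <- function(train_flat, variance_threshold = 0.95) {
  x <- as.matrix(train_flat)
  if (!all(is.finite(x))) stop("non-finite values in input", call. = FALSE)
  n <- nrow(x); d <- ncol(x)
  if (n < 3L) stop("need at least 3 training rows", call. = FALSE)
  if (d < 2L) stop("need at least 2 variables", call. = FALSE)
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must lie in (0, 1]", call. = FALSE)
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  sv <- svd(xc)
  variance <- sv$d^2 / (n - 1)
  ratio <- variance / sum(variance)
  r_max <- min(n - 1L, d)
  if (variance_threshold >= 1) {
    m <- sum(ratio[seq_len(r_max)] > 1e-12)
    m <- max(m, 1L)
  } else {
    m <- which(cumsum(ratio) >= variance_threshold - 1e-12)[1L]
    m <- min(m, r_max)
  }
  rotation <- sv$v[, seq_len(m), drop = FALSE]
  colnames(rotation) <- paste0("PC", seq_len(m))
  rownames(rotation) <- colnames(x)
  scores <- xc %*% rotation
  structure(
    list(center = center, rotation = rotation,
         explained_variance_ratio = ratio[seq_len(m)],
         all_variance_ratio = ratio,
         n_retained = m, variance_threshold = variance_threshold,
         scores = scores),
    class = "pca_model"
  )
}

#' Project data into a fitted PCA space
#'
#' @param model A `pca_model` from [pca_fit()].
#' @param flat Numeric `q x d` matrix with `d` matching the model.
#' @return `q x m` score matrix `(flat - center) %*% rotation`.
#' @export
pca_project <- function(model, flat) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(flat))) flat <- matrix(flat, nrow = 1L)
  flat <- as.matrix(flat)
  if (ncol(flat) != nrow(model$rotation))
    stop("dimension mismatch: model expects ", nrow(model$rotation),
         " variables, got ", ncol(flat), call. = FALSE)
  sweep(flat, 2L, model$center) %*% model$rotation
}
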