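# deterministic derived seeds (kept below 2^31) so distinct learners /
# resamples draw from independent, reproducible streams
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

# draw the B bootstrap resamples (and rebalanced training indices) once,
# so every hyperparameter candidate is evaluated on identical resamples
draw_resamples <- function(n, y, scheme, rebalance, seed) {
  type <- scheme$type %||% "bootstrap"
  B <- if (type == "bootstrap") scheme$B %||% 25L else scheme$K %||% 10L
  set.seed(seed)
  folds <- if (type == "kfold") sample(rep_len(seq_len(B), n)) else NULL
  out <- vector("list", B)
  for (b in seq_len(B)) {
    for (attempt in 1:10) {
      if (type == "bootstrap") {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(idx))
      } else {
        oob <- which(folds == b)
        idx <- setdiff(seq_len(n), oob)
      }
      idx <- rebalance_indices(idx, y, rebalance)
      if (length(oob) && length(unique(y[idx])) == length(unique(y)))
        break
      if (attempt == 10L)
        stop("could not draw a resample containing every class", call. = FALSE)
    }
    out[[b]] <- list(train = idx, oob = oob)
  }
  out
}

# up- or down-sample a training index vector within a resample
rebalance_indices <- function(idx, y, rebalance) {
  if (rebalance == "none") return(idx)
  tab <- table(as.character(y[idx]))
  if (rebalance == "up") {
    target <- max(tab)
    extra <- unlist(lapply(names(tab), function(cl) {
      pool <- idx[y[idx] == cl]
      if (length(pool) < target)
        sample(pool, target - length(pool), replace = TRUE)
      else integer(0)
    }))
    c(idx, extra)
  } else if (rebalance == "down") {
    target <- min(tab)
    unlist(lapply(names(tab), function(cl) {
      pool <- idx[y[idx] == cl]
      sample(pool, target)
    }))
  } else stop("unknown rebalance mode '", rebalance, "'", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resampled evaluation of one hyperparameter candidate
#'
#' Fits the learner on each of B bootstrap resamples (sampled with
#' replacement, size n; optional up-/down-sampling to redress class
#' imbalance within the resample) and scores the chosen metric on the
#' out-of-bag specimens. Resamples whose out-of-bag set misses a class
#' contribute scores computed on the classes available. A k-fold
#' cross-validation scheme is available as an alternative. Fully
#' deterministic given `seed`.
#'
#' @param spec A [learner_spec()].
#' @param params Named list: one hyperparameter combination.
#' @param x,y Training features (matrix) and labels (>= 2 classes).
#' @param scheme `list(type = "bootstrap", B = 25)` (default) or
#'   `list(type = "kfold", K = ...)`.
#' @param metric One of `ROC_AUC`, `Kappa`, `log_loss`, `accuracy`,
#'   `balanced_accuracy`, `F1`.
#' @param rebalance `"none"`, `"up"`, or `"down"`.
#' @param seed Integer seed.
#' @param positive Positive class for binary metrics.
#' @return Numeric vector of per-resample metric values (`NA` where the
#'   metric was undefined on that out-of-bag set).
#' @export
resample_evaluate <- function(spec, params, x, y,
                              scheme = list(type = "bootstrap", B = 25L),
                              metric = "Kappa", rebalance = "none",
                              seed = 1L, positive = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite features", call. = FALSE)
  y <- factor(as.character(y), levels = sort(unique(as.character(y))))
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  resamples <- draw_resamples(nrow(x), y, scheme, rebalance,
                              derive_seed(seed, "resamples"))
  vapply(seq_along(resamples), function(b) {
    rs <- resamples[[b]]
    fit <- tryCatch(
      fit_learner(spec, x[rs$train, , drop = FALSE], y[rs$train], params,
                  seed = derive_seed(seed, "fit", b)),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    probs <- tryCatch(predict_probs(fit, x[rs$oob, , drop = FALSE]),
                      error = function(e) NULL)
    if (is.null(probs)) return(NA_real_)
    metric_score(metric, y[rs$oob], probs, positive)
  }, numeric(1))
}

#' Tune a learner by random discrete hyperparameter search
#'
#' Draws up to `tune_length` distinct combinations uniformly from the
#' learner's discrete hyperparameter space, evaluates each with
#' [resample_evaluate()] on a common set of resamples, keeps the
#' candidate with the best mean metric (direction-aware; ties go to the
#' first drawn), and refits it on the full training partition. Candidates
#' whose every resample fails are discarded; if all candidates fail the
#' learner is marked failed.
#'
#' @inheritParams resample_evaluate
#' @param tune_length Maximum number of candidates to evaluate.
#' @return Object of class `tuned_learner` with fields `spec`,
#'   `best_hyperparameters`, `resample_scores`, `mean_score`,
#'   `fitted_model` (a refit on the full training data), `importances`
#'   (per input variable), `failed`, `seed`.
#' @export
random_search_tune <- function(spec, x, y, tune_length = 10L,
                               scheme = list(type = "bootstrap", B = 25L),
                               metric = "Kappa", rebalance = "none",
                               seed = 1L, positive = NULL) {
  stopifnot(tune_length >= 1L)
  grid <- expand.grid(spec$hyperparameters, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  set.seed(derive_seed(seed, spec$name, "draw"))
  take <- sample.int(nrow(grid), min(tune_length, nrow(grid)))
  candidates <- lapply(take, function(i) as.list(grid[i, , drop = FALSE]))

  asc <- metric_direction(metric) == "ascending"
  best <- NULL
  for (j in seq_along(candidates)) {
    scores <- resample_evaluate(spec, candidates[[j]], x, y, scheme, metric,
                                rebalance, seed = derive_seed(seed, spec$name),
                                positive = positive)
    if (all(is.na(scores))) next
    ms <- mean(scores, na.rm = TRUE)
    better <- is.null(best) ||
      (if (asc) ms < best$mean_score - 1e-12 else ms > best$mean_score + 1e-12)
    if (better)
      best <- list(params = candidates[[j]], scores = scores, mean_score = ms)
  }
  if (is.null(best)) {
    return(structure(list(spec = spec, failed = TRUE, seed = seed,
                          mean_score = NA_real_),
                     class = "tuned_learner"))
  }
  fitted <- tryCatch(
    fit_learner(spec, x, y, best$params, seed = derive_seed(seed, spec$name, "refit")),
    error = function(e) NULL)
  if (is.null(fitted)) {
    return(structure(list(spec = spec, failed = TRUE, seed = seed,
                          mean_score = NA_real_),
                     class = "tuned_learner"))
  }
  imp <- learner_importance(fitted, as.matrix(x), y)
  structure(
    list(spec = spec, best_hyperparameters = best$params,
         resample_scores = best$scores, mean_score = best$mean_score,
         fitted_model = fitted, importances = imp, failed = FALSE,
         metric = metric, seed = seed),
    class = "tuned_learner"
  )
}

#' @export
print.tuned_learner <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat(sprintf("tuned_learner '%s': FAILED\n", x$spec$name))
  } else {
    cat(sprintf("tuned_learner '%s': mean %s = %.4f\n",
                x$spec$name, x$metric, x$mean_score))
  }
  invisible(x)
}

#' Rank tuned learners into a leaderboard
#'
#' Orders successful learners by their mean resampled metric, best first
#' (ascending for log loss, descending otherwise), breaking ties by
#' learner name. Failed learners are excluded.
#'
#' @param tuned List of `tuned_learner` objects.
#' @param metric_name The optimization metric the scores came from.
#' @return Object of class `leaderboard`: list with ordered `entries` and
#'   `metric_name`.
#' @export
rank_learners <- function(tuned, metric_name) {
  tuned <- Filter(function(t) !isTRUE(t$failed), tuned)
  if (!length(tuned)) stop("no successful learners to rank", call. = FALSE)
  scores <- vapply(tuned, function(t) t$mean_score, numeric(1))
  names <- vapply(tuned, function(t) t$spec$name, character(1))
  asc <- metric_direction(metric_name) == "ascending"
  ord <- order(if (asc) scores else -scores, names)
  structure(list(entries = tuned[ord], metric_name = metric_name),
            class = "leaderboard")
}

#' @export
print.leaderboard <- function(x, ...) {
  cat(sprintf("leaderboard (%s):\n", x$metric_name))
  for (i in seq_along(x$entries))
    cat(sprintf("  %2d. %-12s %.4f\n", i, x$entries[[i]]$spec$name,
                x$entries[[i]]$mean_score))
  invisible(x)
}

#' @export
as.data.frame.leaderboard <- function(x, ...) {
  data.frame(
    rank = seq_along(x$entries),
    learner = vapply(x$entries, function(t) t$spec$name, character(1)),
    family = vapply(x$entries, function(t) t$spec$family, character(1)),
    mean_score = vapply(x$entries, function(t) t$mean_score, numeric(1)),
    metric = x$metric_name
  )
}

#' Tune every learner in a registry
#'
#' Convenience wrapper running [random_search_tune()] for each spec (with
#' per-learner derived seeds, so any execution order gives identical
#' results) and ranking the survivors.
#'
#' @inheritParams random_search_tune
#' @param registry Named list of [learner_spec()]s, e.g.
#'   [default_registry()].
#' @return A `leaderboard`.
#' @export
tune_registry <- function(registry, x, y, tune_length = 10L,
                          scheme = list(type = "bootstrap", B = 25L),
                          metric = NULL, rebalance = "none", seed = 1L,
                          positive = NULL) {
  n_classes <- length(unique(as.character(y)))
  if (is.null(metric)) metric <- if (n_classes == 2L) "ROC_AUC" else "Kappa"
  if (n_classes > 2L)
    registry <- Filter(function(s) !s$binary_only, registry)
  tuned <- lapply(registry, function(spec)
    random_search_tune(spec, x, y, tune_length, scheme, metric, rebalance,
                       seed = derive_seed(seed, "tune", spec$name),
                       positive = positive))
  rank_learners(tuned, metric)
}
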