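#' Workflow configuration
#'
#' Collects every tunable of the classification workflow with defaults
#' matching the blending-ensemble conventions: two-stage 15%/15%
#' test/validation split, Tukey fence multiplier 1.5, PCA variance
#' threshold 0.95, bootstrap resampling with B = 25, tune length 10,
#' top-k in {3, 5, 10}, glm and rf metalearners, and the optimization
#' metric chosen by task (ROC AUC for binary, Cohen's kappa for
#' multi-class).
#'
#' @param test_fraction,validation_fraction Split fractions in (0, 0.5).
#' @param split_scheme `"two_stage"` or `"direct"`.
#' @param anomaly_multiplier IQR fence multiplier (`Inf` disables).
#' @param variance_threshold PCA cumulative-variance threshold in (0, 1].
#' @param registry Learner subset: character vector of registry names, or
#'   `NULL` for the full [default_registry()].
#' @param tune_length Random-search candidates per learner.
#' @param resampling `list(type = "bootstrap", B = 25)` or
#'   `list(type = "kfold", K = ...)`.
#' @param rebalance `"none"`, `"up"`, or `"down"`.
#' @param metric Optimization metric, or `NULL` to choose by task.
#' @param top_k Integer vector of ensemble sizes.
#' @param metalearners Subset of `c("glm", "rf")`.
#' @param positive Positive class for binary metrics (`NULL` = first
#'   sorted class).
#' @param average `"macro"` or `"micro"` multi-class averaging.
#' @param n_perm Permutations for the class R-squared p-value (0 = skip).
#' @param seed Master seed; all workflow randomness derives from it via
#'   named substreams.
#' @return A `run_config` list.
#' @export
run_config <- function(test_fraction = 0.15, validation_fraction = 0.15,
                       split_scheme = "two_stage", anomaly_multiplier = 1.5,
                       variance_threshold = 0.95, registry = NULL,
                       tune_length = 10L,
                       resampling = list(type = "bootstrap", B = 25L),
                       rebalance = "none", metric = NULL,
                       top_k = c(3L, 5L, 10L),
                       metalearners = c("glm", "rf"), positive = NULL,
                       average = "macro", n_perm = 0L, seed = 1L) {
  structure(
    list(test_fraction = test_fraction,
         validation_fraction = validation_fraction,
         split_scheme = split_scheme,
         anomaly_multiplier = anomaly_multiplier,
         variance_threshold = variance_threshold, registry = registry,
         tune_length = as.integer(tune_length), resampling = resampling,
         rebalance = rebalance, metric = metric,
         top_k = as.integer(top_k), metalearners = metalearners,
         positive = positive, average = average, n_perm = as.integer(n_perm),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full blending-ensemble workflow
#'
#' Chains every stage on a landmark dataset (or a pre-extracted flat
#' feature table): Procrustes alignment, IQR anomaly filtering,
#' stratified three-way split, PCA fitted on the training partition only,
#' random-search tuning of the registry under bootstrap resampling,
#' leaderboard ranking, top-k blending ensembles with each requested
#' metalearner, and the evaluation-metric table for every base learner
#' and ensemble on the test partition. Dataset-level phenotypic
#' properties are computed on the aligned, filtered data.
#'
#' @param data A [landmark_dataset()], or a list with `features` (matrix)
#'   and `labels` as returned by [read_wide_csv()] in flat mode.
#' @param config A [run_config()].
#' @return A `pipeline_result` list: `aligned`, `filter`, `partition`,
#'   `pca`, `leaderboard`, `ensembles` (named `top<k>_<kind>`),
#'   `metrics` (one row per method), `properties`, `config`.
#' @export
run_pipeline <- function(data, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  flat_mode <- !inherits(data, "landmark_dataset")

  aligned <- NULL
  if (flat_mode) {
    features <- as.matrix(data$features)
    labels <- as.character(data$labels)
    filter <- NULL
  } else {
    aligned <- gpa_align(data)
    filter <- procrustes_iqr_filter(aligned, config$anomaly_multiplier,
                                    labels = aligned$labels)
    keep <- filter$kept
    retained <- subset_landmarks(data, keep)
    aligned <- gpa_align(retained)
    features <- aligned$flat
    labels <- aligned$labels
  }

  part <- stratified_split(labels, config$test_fraction,
                           config$validation_fraction,
                           seed = derive_seed(config$seed, "split"),
                           scheme = config$split_scheme)
  pca <- pca_fit(features[part$train_idx, , drop = FALSE],
                 config$variance_threshold)
  tr_x <- pca$scores
  va_x <- pca_project(pca, features[part$validation_idx, , drop = FALSE])
  te_x <- pca_project(pca, features[part$test_idx, , drop = FALSE])
  tr_y <- labels[part$train_idx]
  va_y <- labels[part$validation_idx]
  te_y <- labels[part$test_idx]

  task <- if (length(unique(labels)) == 2L) "binary" else "multi"
  registry <- default_registry(task)
  if (!is.null(config$registry)) registry <- registry[config$registry]
  metric <- config$metric %||% if (task == "binary") "ROC_AUC" else "Kappa"

  leaderboard <- tune_registry(registry, tr_x, tr_y,
                               tune_length = config$tune_length,
                               scheme = config$resampling, metric = metric,
                               rebalance = config$rebalance,
                               seed = derive_seed(config$seed, "tuning"),
                               positive = config$positive)

  evaluate <- function(labels_pred) {
    cm <- confusion_matrix(labels_pred, te_y)
    rep <- multiclass_metrics(cm, config$average)
    data.frame(accuracy = rep$accuracy, kappa = rep$kappa,
               F1 = rep$macro[["F1"]],
               balanced_accuracy = rep$macro[["balanced_accuracy"]])
  }

  metrics <- NULL
  for (entry in leaderboard$entries) {
    probs <- tryCatch(predict_probs(entry$fitted_model, te_x),
                      error = function(e) NULL)
    if (is.null(probs)) next
    pred <- colnames(probs)[max.col(probs, ties.method = "first")]
    metrics <- rbind(metrics,
                     cbind(method = entry$spec$name, kind = "base",
                           evaluate(pred)))
  }

  ensembles <- list()
  for (k in config$top_k) {
    if (k > length(leaderboard$entries)) next
    for (kind in config$metalearners) {
      ens <- train_blend(leaderboard, k, va_x, va_y, metalearner_kind = kind,
                         seed = derive_seed(config$seed, "blend", k, kind))
      nm <- sprintf("top%d_%s", k, kind)
      ensembles[[nm]] <- ens
      pred <- predict_blend(ens, te_x)
      metrics <- rbind(metrics,
                       cbind(method = nm, kind = "ensemble", evaluate(pred$labels)))
    }
  }

  properties <- if (flat_mode) NULL else dataset_properties(aligned)

  structure(
    list(aligned = aligned, filter = filter, partition = part, pca = pca,
         leaderboard = leaderboard, ensembles = ensembles,
         metrics = metrics, properties = properties, task = task,
         config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %s task, %d base learners, %d ensembles\n",
              x$task, sum(x$metrics$kind == "base"), length(x$ensembles)))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}
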