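#' Stack member predictions into a blended feature matrix
#'
#' Applies each ensemble member to the feature matrix and concatenates
#' their per-class probability blocks column-wise. Block `j` holds member
#' `j`'s probabilities with columns ordered by sorted class label; column
#' names follow the `learner.class` schema.
#'
#' @param members List of `tuned_learner` objects (fitted).
#' @param features `q x m` matrix in the members' training feature space.
#' @param hard_labels If `TRUE`, one-hot encode each member's argmax class
#'   instead of its probabilities (comparison mode).
#' @return `q x (k * C)` matrix with a `"schema"` attribute: a data frame
#'   of (learner, class) column descriptors.
#' @export
stack_predictions <- function(members, features, hard_labels = FALSE) {
  stopifnot(length(members) >= 1L)
  blocks <- lapply(members, function(m) {
    p <- tryCatch(predict_probs(m$fitted_model, features),
                  error = function(e)
                    stop("member '", m$spec$name, "' failed to predict: ",
                         conditionMessage(e), call. = FALSE))
    if (hard_labels) {
      hard <- max.col(p, ties.method = "first")
      p[] <- 0
      p[cbind(seq_len(nrow(p)), hard)] <- 1
    }
    colnames(p) <- paste(m$spec$name, colnames(p), sep = ".")
    p
  })
  out <- do.call(cbind, blocks)
  schema <- do.call(rbind, lapply(members, function(m)
    data.frame(learner = m$spec$name, class = m$fitted_model$levels)))
  attr(out, "schema") <- schema
  out
}

#' Train a blending ensemble from a leaderboard
#'
#' Takes the `top_k` leaderboard entries, stacks their held-out
#' validation-set probability predictions, and fits a metalearner on the
#' stacked matrix against the validation labels: either a ridge-penalized
#' (multinomial) logistic regression (`glm`, lambda = 1e-4 for stability
#' against the collinear member blocks) or a 500-tree random forest
#' (`rf`). Members that fail to predict the validation set are dropped
#' and the next leaderboard entry is promoted. Test data must never enter
#' here; it is only seen by [predict_blend()].
#'
#' Member model-importance weights are read off the metalearner: the sum
#' of absolute coefficients (glm; across outcome equations) or of
#' impurity importances (rf) over each member's column block, normalized
#' to sum to one.
#'
#' @param leaderboard A `leaderboard` from [rank_learners()] /
#'   [tune_registry()].
#' @param top_k Number of members (>= 2), e.g. 3, 5, or 10.
#' @param validation_features,validation_labels The held-out validation
#'   partition (disjoint from training).
#' @param metalearner_kind `"glm"` or `"rf"`.
#' @param seed Integer seed (rf metalearner and any stochastic steps).
#' @param hard_labels Stack one-hot labels instead of probabilities.
#' @return Object of class `blended_ensemble` with `members`,
#'   `metalearner_kind`, `metalearner_model`, `stacked_schema`,
#'   `member_weights` (non-negative, sums to 1), `classes`, `seed`.
#' @export
train_blend <- function(leaderboard, top_k, validation_features,
                        validation_labels,
                        metalearner_kind = c("glm", "rf"), seed = 1L,
                        hard_labels = FALSE) {
  metalearner_kind <- match.arg(metalearner_kind)
  stopifnot(inherits(leaderboard, "leaderboard"))
  if (top_k < 2L) stop("an ensemble needs at least 2 members", call. = FALSE)
  if (top_k > length(leaderboard$entries))
    stop("top_k = ", top_k, " exceeds the ", length(leaderboard$entries),
         " available learners", call. = FALSE)
  y <- factor(as.character(validation_labels),
              levels = sort(unique(as.character(validation_labels))))
  if (nlevels(y) < 2L)
    stop("validation labels contain a single class", call. = FALSE)

  # select top_k members, promoting past any that fail on validation data
  members <- list()
  pool <- leaderboard$entries
  i <- 1L
  while (length(members) < top_k && i <= length(pool)) {
    m <- pool[[i]]
    ok <- tryCatch({
      predict_probs(m$fitted_model, validation_features); TRUE
    }, error = function(e) FALSE)
    if (ok) members[[length(members) + 1L]] <- m
    i <- i + 1L
  }
  if (length(members) < top_k)
    stop("only ", length(members),
         " members predict the validation set; top_k = ", top_k, call. = FALSE)

  z <- stack_predictions(members, validation_features, hard_labels)
  schema <- attr(z, "schema")
  varying <- apply(z, 2L, function(col) diff(range(col)) > 0)

  if (!any(varying)) {
    # fully degenerate stack (every member constant): fall back to the
    # validation class priors
    meta <- list(kind = "prior",
                 probs = as.numeric(table(y)[levels(y)]) / length(y))
    member_weights <- rep(1 / length(members), length(members))
    names(member_weights) <- vapply(members, function(m) m$spec$name,
                                    character(1))
    return(structure(
      list(members = members, metalearner_kind = "prior",
           metalearner_model = meta, stacked_schema = schema,
           member_weights = member_weights, classes = levels(y),
           hard_labels = hard_labels, seed = seed),
      class = "blended_ensemble"))
  }

  if (metalearner_kind == "glm") {
    fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
    set.seed(derive_seed(seed, "meta"))
    # stacked probabilities already share the [0, 1] scale, so the ridge
    # penalty and the block coefficient weights stay comparable without
    # per-column standardization
    meta <- withCallingHandlers(
      glmnet::glmnet(z, y, family = fam, alpha = 0, lambda = 1e-4,
                     standardize = FALSE),
      warning = function(w) {
        # small validation classes are the norm in blending; glmnet's
        # advisory about them is expected, everything else propagates
        if (grepl("fewer than 8", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    cf <- coef(meta, s = 1e-4)
    colw <- if (is.list(cf)) {
      Reduce(`+`, lapply(cf, function(b) abs(as.matrix(b)[-1L, 1L])))
    } else abs(as.matrix(cf)[-1L, 1L])
  } else {
    set.seed(derive_seed(seed, "meta"))
    # constant stacked columns carry no information and can stall the
    # forest's split search; fit on the varying columns only
    meta <- randomForest::randomForest(z[, varying, drop = FALSE], y,
                                       ntree = 500)
    meta$.varying <- varying
    colw <- stats::setNames(rep(0, ncol(z)), colnames(z))
    colw[varying] <- randomForest::importance(meta)[, "MeanDecreaseGini"]
  }
  member_names <- vapply(members, function(m) m$spec$name, character(1))
  block <- schema$learner
  member_weights <- vapply(member_names, function(nm)
    sum(colw[block == nm]), numeric(1))
  if (sum(member_weights) <= 0)
    member_weights[] <- 1 / length(member_weights)
  else
    member_weights <- member_weights / sum(member_weights)

  structure(
    list(members = members, metalearner_kind = metalearner_kind,
         metalearner_model = meta, stacked_schema = schema,
         member_weights = member_weights, classes = levels(y),
         hard_labels = hard_labels, seed = seed),
    class = "blended_ensemble"
  )
}

#' @export
print.blended_ensemble <- function(x, ...) {
  cat(sprintf("blended_ensemble: top-%d members, %s metalearner, %d classes\n",
              length(x$members), x$metalearner_kind, length(x$classes)))
  w <- sprintf("%s (%.2f)", names(x$member_weights), x$member_weights)
  cat("  member weights:", paste(w, collapse = ", "), "\n")
  invisible(x)
}

#' Predict classes with a blending ensemble
#'
#' Stacks the members' predictions on new features and applies the
#' metalearner. Labels are the argmax of the ensemble probabilities (ties
#' broken toward the first class in sorted order).
#'
#' @param ensemble A `blended_ensemble`.
#' @param features `q x m` matrix in the members' feature space.
#' @return List with `labels` (length q) and `probabilities`
#'   (`q x C`, rows summing to 1).
#' @export
predict_blend <- function(ensemble, features) {
  stopifnot(inherits(ensemble, "blended_ensemble"))
  z <- stack_predictions(ensemble$members, features, ensemble$hard_labels)
  if (ensemble$metalearner_kind == "prior") {
    p <- matrix(ensemble$metalearner_model$probs, nrow(z),
                length(ensemble$classes), byrow = TRUE,
                dimnames = list(NULL, ensemble$classes))
    return(list(labels = ensemble$classes[max.col(p, ties.method = "first")],
                probabilities = p))
  }
  if (ensemble$metalearner_kind == "glm") {
    p <- predict(ensemble$metalearner_model, z, s = 1e-4, type = "response")
    if (length(dim(p)) == 3L) {
      p <- p[, , 1L]
      if (is.null(dim(p)))
        p <- matrix(p, nrow = 1L, dimnames = list(NULL, ensemble$classes))
    } else {
      p <- cbind(1 - p[, 1L], p[, 1L])
      colnames(p) <- ensemble$classes
    }
  } else {
    keep <- ensemble$metalearner_model$.varying
    p <- predict(ensemble$metalearner_model, z[, keep, drop = FALSE],
                 type = "prob")
  }
  p <- align_probs(p, ensemble$classes)
  list(labels = ensemble$classes[max.col(p, ties.method = "first")],
       probabilities = p)
}

#' Weighted ensemble variable importance
#'
#' Combines the members' per-variable importances into a single map: each
#' member's importances are normalized to sum to one, multiplied by that
#' member's model-importance weight from the metalearner, and summed.
#' The result sums to one.
#'
#' @param ensemble A `blended_ensemble`.
#' @param member_variable_importances Optional list of named non-negative
#'   vectors, one per member over a common variable set; defaults to the
#'   importances stored on each member at tuning time.
#' @return Named numeric vector over the input variables, summing to 1.
#' @export
ensemble_importance <- function(ensemble, member_variable_importances = NULL) {
  stopifnot(inherits(ensemble, "blended_ensemble"))
  maps <- member_variable_importances %||%
    lapply(ensemble$members, function(m) m$importances)
  if (length(maps) != length(ensemble$members))
    stop("need one importance map per member", call. = FALSE)
  vars <- names(maps[[1L]])
  for (m in maps) {
    if (!setequal(names(m), vars))
      stop("member importance maps cover different variables", call. = FALSE)
    if (any(m < 0)) stop("importances must be non-negative", call. = FALSE)
  }
  weighted_importance(maps, ensemble$member_weights)
}

#' Weighted mean of normalized importance maps
#'
#' The aggregation rule behind [ensemble_importance()], usable on its
#' own: each map is normalized to sum to one, scaled by its weight, and
#' the maps are summed. A single map (k = 1) simply returns that map
#' normalized.
#'
#' @param maps List of named non-negative numeric vectors over a common
#'   variable set.
#' @param weights Non-negative weights, one per map (normalized
#'   internally).
#' @return Named numeric vector summing to 1.
#' @export
weighted_importance <- function(maps, weights = rep(1, length(maps))) {
  if (!length(maps)) stop("no importance maps given", call. = FALSE)
  if (length(weights) != length(maps))
    stop("need one weight per map", call. = FALSE)
  vars <- names(maps[[1L]])
  for (m in maps) {
    if (!setequal(names(m), vars))
      stop("importance maps cover different variables", call. = FALSE)
    if (any(m < 0)) stop("importances must be non-negative", call. = FALSE)
  }
  norm <- lapply(maps, function(m) {
    s <- sum(m)
    if (s <= 0) stop("all-zero member importances", call. = FALSE)
    m[vars] / s
  })
  weights <- weights / sum(weights)
  out <- Reduce(`+`, Map(function(m, wi) m * wi, norm, weights))
  out / sum(out)
}
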