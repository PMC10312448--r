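#' @importFrom stats predict rnorm runif quantile sd cor coef glm binomial
NULL

#' Define a base-learner specification
#'
#' @param name Unique short name (used in leaderboards and stacked-column
#'   schemas).
#' @param family One of `bayesian`, `tree`, `bagging_boosting`,
#'   `discriminant`, `kernel_instance`, `neural`, `regression`.
#' @param hyperparameters Named list of discrete candidate vectors (a
#'   single default point is allowed); the random search draws
#'   combinations from their Cartesian product.
#' @param fit `function(x, y, params)` returning a fitted model; `x` is a
#'   numeric matrix, `y` a factor with sorted levels.
#' @param prob `function(model, x)` returning an `n x C` probability
#'   matrix with columns named and ordered by the sorted class levels.
#' @param importance Optional `function(model, x, y)` returning a named
#'   non-negative vector over the columns of `x`; when `NULL` a
#'   one-vs-rest AUC filter importance is used.
#' @param supports_probabilities Whether `prob` returns genuine
#'   probabilities (learners without native probability output expose
#'   degenerate one-hot "probabilities" and set this to `FALSE`).
#' @param binary_only If `TRUE` the learner is excluded from multi-class
#'   registries.
#' @return Object of class `learner_spec`.
#' @export
learner_spec <- function(name, family, hyperparameters, fit, prob,
                         importance = NULL, supports_probabilities = TRUE,
                         binary_only = FALSE) {
  families <- c("bayesian", "tree", "bagging_boosting", "discriminant",
                "kernel_instance", "neural", "regression")
  if (!family %in% families)
    stop("unknown learner family '", family, "'", call. = FALSE)
  if (!length(hyperparameters))
    stop("hyperparameter space must be non-empty (a single default point is fine)",
         call. = FALSE)
  structure(
    list(name = name, family = family, hyperparameters = hyperparameters,
         fit = fit, prob = prob, importance = importance,
         supports_probabilities = supports_probabilities,
         binary_only = binary_only),
    class = "learner_spec"
  )
}

#' @export
print.learner_spec <- function(x, ...) {
  cat(sprintf("learner_spec '%s' (family %s)%s\n", x$name, x$family,
              if (x$binary_only) " [binary only]" else ""))
  invisible(x)
}

# reorder/complete a probability matrix so columns are exactly `levels`
align_probs <- function(p, levels) {
  p <- as.matrix(p)
  out <- matrix(0, nrow(p), length(levels), dimnames = list(NULL, levels))
  hit <- intersect(colnames(p), levels)
  out[, hit] <- p[, hit]
  rs <- rowSums(out)
  rs[rs == 0] <- 1
  out / rs
}

# ---- hand-implemented learners -------------------------------------------

# Friedman-style regularized discriminant analysis. lambda blends each
# class covariance with the pooled covariance; gamma shrinks toward a
# scaled identity. lambda = 1, gamma = 0 recovers LDA; lambda = 0, QDA.
fit_rda <- function(x, y, lambda, gamma) {
  classes <- levels(y)
  d <- ncol(x)
  n <- nrow(x)
  mu <- lapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]))
  sw <- lapply(classes, function(cl) {
    xc <- sweep(x[y == cl, , drop = FALSE], 2L, colMeans(x[y == cl, , drop = FALSE]))
    crossprod(xc)
  })
  pooled <- Reduce(`+`, sw) / (n - length(classes))
  prior <- as.numeric(table(y)[classes]) / n
  covs <- lapply(seq_along(classes), function(i) {
    n_i <- sum(y == classes[i])
    num <- (1 - lambda) * sw[[i]] + lambda * pooled * (n - length(classes))
    den <- (1 - lambda) * max(n_i - 1L, 1L) + lambda * (n - length(classes))
    s <- num / den
    s <- (1 - gamma) * s + gamma * (sum(diag(s)) / d) * diag(d)
    s + 1e-8 * diag(d)  # numerical floor
  })
  chols <- lapply(covs, chol)
  list(classes = classes, mu = mu, chols = chols, prior = prior)
}

predict_rda <- function(model, x) {
  x <- as.matrix(x)
  logd <- vapply(seq_along(model$classes), function(i) {
    ch <- model$chols[[i]]
    z <- forwardsolve(t(ch), t(sweep(x, 2L, model$mu[[i]])))
    -0.5 * colSums(z^2) - sum(log(diag(ch))) + log(model$prior[i])
  }, numeric(nrow(x)))
  logd <- matrix(logd, nrow = nrow(x))
  logd <- logd - apply(logd, 1L, max)
  p <- exp(logd)
  p <- p / rowSums(p)
  colnames(p) <- model$classes
  p
}

# SAMME adaptive boosting over rpart trees (multi-class AdaBoost).
fit_adaboost <- function(x, y, n_trees, maxdepth, learn_rate) {
  n <- nrow(x)
  C <- nlevels(y)
  df <- data.frame(.y = y, x, check.names = FALSE)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(n_trees)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, xval = 0,
                          minsplit = 4))
    pred <- predict(fit, df, type = "class")
    miss <- pred != y
    err <- sum(w[miss])
    if (err <= 1e-12) {  # perfect stump dominates; keep it and stop
      trees[[length(trees) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 1 - 1 / C) break
    alpha <- learn_rate * (log((1 - err) / err) + log(C - 1))
    trees[[length(trees) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (!length(trees)) {  # fall back to a single unweighted tree
    trees <- list(rpart::rpart(.y ~ ., data = df,
                               control = rpart::rpart.control(
                                 maxdepth = maxdepth, cp = 0, xval = 0)))
    alphas <- 1
  }
  list(trees = trees, alphas = alphas, classes = levels(y))
}

predict_adaboost <- function(model, x) {
  df <- data.frame(as.matrix(x), check.names = FALSE)
  votes <- matrix(0, nrow(df), length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (m in seq_along(model$trees)) {
    pred <- as.character(predict(model$trees[[m]], df, type = "class"))
    votes[cbind(seq_len(nrow(df)), match(pred, model$classes))] <-
      votes[cbind(seq_len(nrow(df)), match(pred, model$classes))] + model$alphas[m]
  }
  votes / rowSums(votes)
}

importance_adaboost <- function(model) {
  out <- numeric(0)
  for (m in seq_along(model$trees)) {
    vi <- model$trees[[m]]$variable.importance
    if (is.null(vi)) next
    vi <- vi * model$alphas[m]
    for (v in names(vi)) out[v] <- sum(out[v], vi[v], na.rm = TRUE)
  }
  out
}

# model-free fallback importance: one-vs-rest AUC separation per variable
filter_importance <- function(x, y) {
  y <- as.factor(y)
  apply(as.matrix(x), 2L, function(col) {
    max(vapply(levels(y), function(cl) {
      abs(roc_auc(col, ifelse(y == cl, "pos", "neg"), positive = "pos") - 0.5)
    }, numeric(1))) * 2
  })
}

# ---- registry -------------------------------------------------------------

#' Default base-learner registry
#'
#' Returns the built-in family-spanning set of classifier specifications:
#' naive Bayes; a decision tree; random forest; adaptive boosting (SAMME)
#' and bagged trees; linear, quadratic, and regularized discriminant
#' analysis; k-nearest neighbours; linear, polynomial, and radial-kernel
#' support vector machines; a single-hidden-layer neural network;
#' penalized multinomial regression and a plain logistic model; and
#' partial-least-squares discriminant analysis. Learners flagged
#' `binary_only` are excluded when `task = "multi"`.
#'
#' @param task `"binary"` or `"multi"`.
#' @return Named list of [learner_spec()] objects.
#' @export
default_registry <- function(task = c("binary", "multi")) {
  task <- match.arg(task)
  specs <- list(

    nb = learner_spec(
      "nb", "bayesian",
      list(laplace = c(0, 0.5, 1)),
      fit = function(x, y, p) e1071::naiveBayes(x, y, laplace = p$laplace),
      prob = function(m, x) predict(m, as.matrix(x), type = "raw")),

    cart = learner_spec(
      "cart", "tree",
      list(cp = 10^seq(-4, -1, length.out = 10)),
      fit = function(x, y, p) {
        df <- data.frame(.y = y, x, check.names = FALSE)
        rpart::rpart(.y ~ ., data = df,
                     control = rpart::rpart.control(cp = p$cp, xval = 0))
      },
      prob = function(m, x)
        predict(m, data.frame(as.matrix(x), check.names = FALSE), type = "prob"),
      importance = function(m, x, y) {
        vi <- m$variable.importance
        if (is.null(vi)) stats::setNames(rep(0, ncol(x)), colnames(x)) else vi
      }),

    rf = learner_spec(
      "rf", "tree",
      list(mtry_frac = c(0.1, 0.2, 0.33, 0.5, 0.7, 0.9)),
      fit = function(x, y, p) {
        mtry <- max(1L, round(p$mtry_frac * ncol(x)))
        randomForest::randomForest(x, y, mtry = mtry, ntree = 500)
      },
      prob = function(m, x) predict(m, as.matrix(x), type = "prob"),
      importance = function(m, x, y)
        randomForest::importance(m)[, "MeanDecreaseGini"]),

    adaboost = learner_spec(
      "adaboost", "bagging_boosting",
      list(n_trees = c(25, 50, 100), maxdepth = c(1, 2, 3),
           learn_rate = c(0.3, 1)),
      fit = function(x, y, p)
        fit_adaboost(x, y, p$n_trees, p$maxdepth, p$learn_rate),
      prob = function(m, x) predict_adaboost(m, x),
      importance = function(m, x, y) importance_adaboost(m)),

    treebag = learner_spec(
      "treebag", "bagging_boosting",
      list(nbagg = c(10, 25, 50)),
      fit = function(x, y, p) {
        df <- data.frame(.y = y, x, check.names = FALSE)
        ipred::bagging(.y ~ ., data = df, nbagg = p$nbagg, coob = FALSE)
      },
      prob = function(m, x)
        predict(m, data.frame(as.matrix(x), check.names = FALSE), type = "prob")),

    lda = learner_spec(
      "lda", "discriminant",
      list(default = TRUE),
      fit = function(x, y, p) MASS::lda(x, grouping = y),
      prob = function(m, x) predict(m, as.matrix(x))$posterior),

    qda = learner_spec(
      "qda", "discriminant",
      list(default = TRUE),
      fit = function(x, y, p) MASS::qda(x, grouping = y),
      prob = function(m, x) predict(m, as.matrix(x))$posterior),

    rda = learner_spec(
      "rda", "discriminant",
      list(lambda = c(0, 0.25, 0.5, 0.75, 1), gamma = c(0, 0.25, 0.5, 0.75)),
      fit = function(x, y, p) fit_rda(x, y, p$lambda, p$gamma),
      prob = function(m, x) predict_rda(m, x)),

    knn = learner_spec(
      "knn", "kernel_instance",
      list(k = seq(1, 31, by = 2)),
      fit = function(x, y, p) caret::knn3(as.matrix(x), y, k = p$k),
      prob = function(m, x) predict(m, as.matrix(x), type = "prob")),

    svm_linear = learner_spec(
      "svm_linear", "kernel_instance",
      list(cost = 10^seq(-2, 2, length.out = 9)),
      fit = function(x, y, p)
        e1071::svm(x, y, kernel = "linear", cost = p$cost, probability = TRUE),
      prob = function(m, x)
        attr(predict(m, as.matrix(x), probability = TRUE), "probabilities")),

    svm_poly = learner_spec(
      "svm_poly", "kernel_instance",
      list(cost = 10^seq(-2, 2, length.out = 5), degree = c(2, 3)),
      fit = function(x, y, p)
        e1071::svm(x, y, kernel = "polynomial", degree = p$degree,
                   cost = p$cost, probability = TRUE),
      prob = function(m, x)
        attr(predict(m, as.matrix(x), probability = TRUE), "probabilities")),

    svm_rbf = learner_spec(
      "svm_rbf", "kernel_instance",
      list(cost = 10^seq(-2, 2, length.out = 5), gamma_scale = c(0.5, 1, 2)),
      fit = function(x, y, p)
        e1071::svm(x, y, kernel = "radial", cost = p$cost,
                   gamma = p$gamma_scale / ncol(x), probability = TRUE),
      prob = function(m, x)
        attr(predict(m, as.matrix(x), probability = TRUE), "probabilities")),

    nnet = learner_spec(
      "nnet", "neural",
      list(size = c(1, 3, 5, 8, 12), decay = c(0, 1e-4, 1e-3, 1e-2, 1e-1)),
      fit = function(x, y, p) {
        ymat <- nnet::class.ind(y)
        m <- nnet::nnet(as.matrix(x), ymat, size = p$size, decay = p$decay,
                        softmax = TRUE, maxit = 250, trace = FALSE,
                        MaxNWts = 10000)
        m$classes <- levels(y)
        m
      },
      prob = function(m, x) {
        p <- predict(m, as.matrix(x))
        colnames(p) <- m$classes
        p
      }),

    glmnet = learner_spec(
      "glmnet", "regression",
      list(alpha = c(0, 0.5, 1), lambda = 10^seq(-4, 0, length.out = 7)),
      fit = function(x, y, p) {
        fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
        m <- glmnet::glmnet(as.matrix(x), y, family = fam, alpha = p$alpha,
                            lambda = p$lambda)
        m$.lambda <- p$lambda
        m$.classes <- levels(y)
        m
      },
      prob = function(m, x) {
        p <- predict(m, as.matrix(x), s = m$.lambda, type = "response")
        if (length(dim(p)) == 3L) {
          p <- p[, , 1L]
          if (is.null(dim(p))) p <- matrix(p, nrow = 1L,
                                           dimnames = list(NULL, m$.classes))
        } else {
          p <- cbind(1 - p[, 1L], p[, 1L])
          colnames(p) <- m$.classes
        }
        p
      },
      importance = function(m, x, y) {
        cf <- coef(m, s = m$.lambda)
        if (is.list(cf)) {
          v <- Reduce(`+`, lapply(cf, function(b) abs(as.matrix(b)[-1L, 1L])))
        } else {
          v <- abs(as.matrix(cf)[-1L, 1L])
        }
        v
      }),

    glm_logistic = learner_spec(
      "glm_logistic", "regression",
      list(default = TRUE),
      fit = function(x, y, p) {
        df <- data.frame(.y = y, x, check.names = FALSE)
        m <- glm(.y ~ ., data = df, family = binomial())
        m$.classes <- levels(y)
        m
      },
      prob = function(m, x) {
        p <- predict(m, data.frame(as.matrix(x), check.names = FALSE),
                     type = "response")
        out <- cbind(1 - p, p)
        colnames(out) <- m$.classes
        out
      },
      binary_only = TRUE),

    plsda = learner_spec(
      "plsda", "regression",
      list(ncomp = 1:8),
      fit = function(x, y, p) {
        m <- mixOmics::plsda(as.matrix(x),
                             y, ncomp = min(p$ncomp, ncol(x)))
        m$.ncomp <- min(p$ncomp, ncol(x))
        m
      },
      prob = function(m, x) {
        pr <- predict(m, as.matrix(x))$predict[, , m$.ncomp]
        if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L,
                                           dimnames = list(NULL, colnames(m$Y)))
        # dummy-response predictions mapped to the simplex by softmax
        e <- exp(5 * (pr - apply(pr, 1L, max)))
        e / rowSums(e)
      })
  )

  specs <- lapply(specs, function(s) { s })
  if (task == "multi")
    specs <- Filter(function(s) !s$binary_only, specs)
  specs
}

# fit one learner and wrap prediction so probability columns always match
# the sorted class levels of the training labels
fit_learner <- function(spec, x, y, params, seed = NULL) {
  y <- factor(as.character(y), levels = sort(unique(as.character(y))))
  if (!is.null(seed)) set.seed(seed)
  model <- spec$fit(as.matrix(x), y, params)
  structure(list(spec_name = spec$name, model = model, levels = levels(y),
                 params = params, spec = spec),
            class = "fitted_learner")
}

# class-probability predictions from a fitted_learner, columns = levels
predict_probs <- function(fitted, x) {
  p <- fitted$spec$prob(fitted$model, as.matrix(x))
  align_probs(p, fitted$levels)
}

# per-variable importances for a fitted learner (native or AUC filter),
# returned over all columns of x, non-negative
learner_importance <- function(fitted, x, y) {
  vars <- colnames(x)
  v <- NULL
  if (!is.null(fitted$spec$importance))
    v <- tryCatch(fitted$spec$importance(fitted$model, x, y), error = function(e) NULL)
  if (is.null(v) || !length(v) || all(v == 0))
    v <- filter_importance(x, y)
  out <- stats::setNames(rep(0, length(vars)), vars)
  hit <- intersect(names(v), vars)
  out[hit] <- pmax(as.numeric(v[hit]), 0)
  out
}
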