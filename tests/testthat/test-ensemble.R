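# deterministic toy members used to probe the stacking machinery
make_tuned <- function(spec, x, y, score = 0.9, seed = 1) {
  fit <- morphoblend:::fit_learner(spec, x, y, lapply(spec$hyperparameters, `[[`, 1),
                     seed = seed)
  structure(list(spec = spec, best_hyperparameters = list(),
                 resample_scores = score, mean_score = score,
                 fitted_model = fit,
                 importances = morphoblend:::filter_importance(x, y),
                 failed = FALSE, metric = "accuracy", seed = seed),
            class = "tuned_learner")
}

perfect_spec <- learner_spec(
  "perfect", "kernel_instance", list(default = TRUE),
  fit = function(x, y, p) list(levels = levels(y)),
  prob = function(m, x) {
    # Bayes rule for make_blobs(sep = 8): c2 lives at +8 on axis 2,
    # c1 at the origin, so the midpoint 4 separates them
    p <- (sign(x[, 2] - 4) + 1) / 2
    cbind(c1 = 1 - p, c2 = p)
  })

noise_spec <- learner_spec(
  "noise", "kernel_instance", list(default = TRUE),
  fit = function(x, y, p) list(levels = levels(y)),
  prob = function(m, x) {
    # depends only on an uninformative coordinate
    p <- plogis(x[, 1] * 0.1)
    cbind(c1 = 1 - p, c2 = p)
  })

constant_spec <- learner_spec(
  "constant", "bayesian", list(default = TRUE),
  fit = function(x, y, p) list(levels = levels(y)),
  prob = function(m, x)
    matrix(rep(c(1, 0), each = nrow(x)), ncol = 2,
           dimnames = list(NULL, c("c1", "c2"))),
  supports_probabilities = FALSE)

test_that("stacked matrices have the schema layout with unit row sums per block", {
  blobs <- make_blobs(n_per = 20, d = 3, sep = 6, seed = 1, classes = 3)
  reg <- default_registry("multi")
  members <- list(make_tuned(reg$lda, blobs$x, blobs$y),
                  make_tuned(reg$knn, blobs$x, blobs$y))
  z <- stack_predictions(members, blobs$x[1:5, ])
  expect_identical(dim(z), c(5L, 6L))
  schema <- attr(z, "schema")
  expect_identical(schema$learner, rep(c("lda", "knn"), each = 3))
  expect_identical(colnames(z)[1:3], c("lda.c1", "lda.c2", "lda.c3"))
  for (block in list(1:3, 4:6))
    expect_true(all(abs(rowSums(z[, block]) - 1) < 1e-6))
  expect_identical(z, stack_predictions(members, blobs$x[1:5, ]))
})

test_that("a constant member stacks as a one-hot block", {
  blobs <- make_blobs(n_per = 10, sep = 6, seed = 2)
  member <- make_tuned(constant_spec, blobs$x, blobs$y)
  z <- stack_predictions(list(member), blobs$x)
  expect_true(all(z[, "constant.c1"] == 1))
  expect_true(all(z[, "constant.c2"] == 0))
})

test_that("blending a perfect and a noise member leans on the perfect one", {
  for (seed in 1:5) {
    blobs <- make_blobs(n_per = 60, d = 3, sep = 8, seed = seed)
    part <- stratified_split(blobs$y, seed = seed)
    members <- list(make_tuned(perfect_spec, blobs$x[part$train_idx, ],
                               blobs$y[part$train_idx], score = 0.99),
                    make_tuned(noise_spec, blobs$x[part$train_idx, ],
                               blobs$y[part$train_idx], score = 0.5))
    lb <- structure(list(entries = members, metric_name = "accuracy"),
                    class = "leaderboard")
    ens <- train_blend(lb, 2, blobs$x[part$validation_idx, ],
                       blobs$y[part$validation_idx], "glm", seed = seed)
    expect_gt(ens$member_weights[["perfect"]], 0.6)
    pred <- predict_blend(ens, blobs$x[part$test_idx, ])
    acc_ens <- mean(pred$labels == blobs$y[part$test_idx])
    expect_gte(acc_ens, 1.0 - 0.02)  # within 2% of the perfect member
  }
})

test_that("blend training and prediction are deterministic given the seed", {
  blobs <- make_blobs(n_per = 40, sep = 4, seed = 3)
  part <- stratified_split(blobs$y, seed = 3)
  reg <- default_registry("binary")
  lb <- tune_registry(reg[c("lda", "knn", "cart")],
                      blobs$x[part$train_idx, ], blobs$y[part$train_idx],
                      tune_length = 2, scheme = fast_scheme, seed = 5)
  run <- function(kind) {
    ens <- train_blend(lb, 3, blobs$x[part$validation_idx, ],
                       blobs$y[part$validation_idx], kind, seed = 11)
    predict_blend(ens, blobs$x[part$test_idx, ])
  }
  for (kind in c("glm", "rf")) {
    p1 <- run(kind); p2 <- run(kind)
    expect_identical(p1$labels, p2$labels)
    expect_equal(p1$probabilities, p2$probabilities, tolerance = 1e-12)
    expect_true(all(abs(rowSums(p1$probabilities) - 1) < 1e-6))
  }
})

test_that("top_k beyond the leaderboard and single-class validation labels error", {
  blobs <- make_blobs(n_per = 30, sep = 6, seed = 4)
  reg <- default_registry("binary")
  lb <- tune_registry(reg[c("lda", "knn")], blobs$x, blobs$y,
                      tune_length = 1, scheme = fast_scheme, seed = 6)
  expect_error(train_blend(lb, 5, blobs$x, blobs$y, "glm"), "exceeds")
  expect_error(train_blend(lb, 2, blobs$x, rep("c1", nrow(blobs$x)), "glm"),
               "single class")
})

test_that("an ensemble of constant predictors predicts that constant class", {
  blobs <- make_blobs(n_per = 25, sep = 6, seed = 5)
  keep <- c(which(blobs$y == "c1"), which(blobs$y == "c2")[1:6])
  x <- blobs$x[keep, ]; y <- blobs$y[keep]
  members <- list(make_tuned(constant_spec, x, y),
                  make_tuned(constant_spec, x, y))
  members[[2]]$spec$name <- "constant2"
  lb <- structure(list(entries = members, metric_name = "accuracy"),
                  class = "leaderboard")
  ens <- train_blend(lb, 2, x, y, "rf", seed = 2)
  pred <- predict_blend(ens, x)
  expect_true(all(pred$labels == "c1"))
})

test_that("removing a near-zero-weight member barely changes predictions", {
  blobs <- make_blobs(n_per = 80, d = 3, sep = 8, seed = 6)
  part <- stratified_split(blobs$y, seed = 6)
  tr <- part$train_idx; va <- part$validation_idx; te <- part$test_idx
  m_perfect <- make_tuned(perfect_spec, blobs$x[tr, ], blobs$y[tr], 0.99)
  m_perfect2 <- make_tuned(perfect_spec, blobs$x[tr, ], blobs$y[tr], 0.99)
  m_perfect2$spec$name <- "perfect2"
  m_const <- make_tuned(constant_spec, blobs$x[tr, ], blobs$y[tr], 0.5)
  lb3 <- structure(list(entries = list(m_perfect, m_perfect2, m_const),
                        metric_name = "accuracy"), class = "leaderboard")
  lb2 <- structure(list(entries = list(m_perfect, m_perfect2),
                        metric_name = "accuracy"), class = "leaderboard")
  e3 <- train_blend(lb3, 3, blobs$x[va, ], blobs$y[va], "glm", seed = 7)
  e2 <- train_blend(lb2, 2, blobs$x[va, ], blobs$y[va], "glm", seed = 7)
  expect_lt(e3$member_weights[["constant"]], 0.2)
  p3 <- predict_blend(e3, blobs$x[te, ])$labels
  p2 <- predict_blend(e2, blobs$x[te, ])$labels
  expect_gte(mean(p3 == p2), 0.99)
})

test_that("weighted importance reduces to hand-computed cases", {
  m1 <- c(v1 = 1, v2 = 0)
  m2 <- c(v1 = 0, v2 = 1)
  expect_equal(weighted_importance(list(m1), 1), c(v1 = 1, v2 = 0))
  expect_equal(weighted_importance(list(m1, m2), c(0.5, 0.5)),
               c(v1 = 0.5, v2 = 0.5))
  expect_equal(weighted_importance(list(m1, m2), c(0.75, 0.25)),
               c(v1 = 0.75, v2 = 0.25))
  # un-normalized member maps are normalized first
  expect_equal(weighted_importance(list(c(v1 = 10, v2 = 10), m2), c(.5, .5)),
               c(v1 = 0.25, v2 = 0.75))
  expect_error(weighted_importance(list(c(v1 = 0, v2 = 0)), 1), "all-zero")
  expect_error(weighted_importance(list(m1, c(a = 1, b = 0)), c(.5, .5)),
               "different variables")
})

test_that("ensemble importance sums to one over the input variables", {
  blobs <- make_blobs(n_per = 40, sep = 5, seed = 8)
  part <- stratified_split(blobs$y, seed = 8)
  reg <- default_registry("binary")
  lb <- tune_registry(reg[c("lda", "cart", "knn")],
                      blobs$x[part$train_idx, ], blobs$y[part$train_idx],
                      tune_length = 2, scheme = fast_scheme, seed = 9)
  ens <- train_blend(lb, 3, blobs$x[part$validation_idx, ],
                     blobs$y[part$validation_idx], "glm", seed = 10)
  imp <- ensemble_importance(ens)
  expect_equal(sum(imp), 1, tolerance = 1e-8)
  expect_true(all(imp >= 0))
  expect_setequal(names(imp), colnames(blobs$x))
})
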