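test_that("class R-squared handles exact degenerate cases", {
  x <- matrix(c(0, 0, 1, 1), ncol = 1)
  expect_equal(class_r2(x, c("a", "a", "b", "b")), 1)
  x2 <- matrix(c(0, 1, 0, 1), ncol = 1)
  expect_equal(class_r2(x2, c("a", "a", "b", "b")), 0)
  expect_error(class_r2(matrix(rnorm(6), 3), c("a", "a", "b")), "single member")
})

test_that("class R-squared equals a brute-force sums-of-squares double loop", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    d <- 4
    x <- matrix(rnorm(n * d), n, d)
    labels <- sample(c("a", "b", "c"), n, replace = TRUE)
    while (min(table(labels)) < 2)
      labels <- sample(c("a", "b", "c"), n, replace = TRUE)
    # oracle: explicit per-element loops
    grand <- colMeans(x)
    ss_t <- 0; ss_w <- 0
    for (i in seq_len(n)) for (j in seq_len(d)) {
      ss_t <- ss_t + (x[i, j] - grand[j])^2
      mu <- mean(x[labels == labels[i], j])
      ss_w <- ss_w + (x[i, j] - mu)^2
    }
    expect_equal(class_r2(x, labels), 1 - ss_w / ss_t, tolerance = 1e-10)
  }
})

test_that("class R-squared permutation p-value is small for separated classes", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20))
  r2 <- class_r2(x, rep(c("a", "b"), each = 20), n_perm = 199, seed = 2)
  expect_lt(attr(r2, "p_value"), 0.05)
})

test_that("covariance distance is zero for identical class covariances and averages all pairs", {
  set.seed(6)
  base <- matrix(rnorm(30 * 3), 30, 3)
  x <- rbind(base, sweep(base, 2, c(5, 0, 0)))  # shifted copy: same covariance
  labels <- rep(c("a", "b"), each = 30)
  expect_equal(mean_class_cov_distance(x, labels), 0, tolerance = 1e-12)

  x3 <- rbind(base, base * 2, base * 3)
  lab3 <- rep(c("a", "b", "c"), each = 30)
  covs <- lapply(list(base, base * 2, base * 3), cov)
  manual <- mean(c(sqrt(sum((covs[[1]] - covs[[2]])^2)),
                   sqrt(sum((covs[[1]] - covs[[3]])^2)),
                   sqrt(sum((covs[[2]] - covs[[3]])^2))))
  expect_equal(mean_class_cov_distance(x3, lab3), manual, tolerance = 1e-12)
  expect_error(mean_class_cov_distance(rbind(base, base[1:2, ]),
                                       c(rep("a", 30), "b", "b")), "too small")
})

test_that("covariance distance between I and 2I populations approaches sqrt(d)", {
  d <- 4
  for (seed in 1:3) {
    set.seed(seed)
    x <- rbind(matrix(rnorm(2000 * d), 2000, d),
               matrix(rnorm(2000 * d, sd = sqrt(2)), 2000, d))
    labels <- rep(c("a", "b"), each = 2000)
    est <- mean_class_cov_distance(x, labels)
    expect_lt(abs(est - sqrt(d)) / sqrt(d), 0.10)
  }
})

test_that("mean class shape distance is exactly zero for identical class means without noise", {
  sp <- synthetic_spec(n_classes = 3, class_counts = 10, p = 8, delta = 0,
                       noise_sd = 0, nuisance = FALSE, seed = 3)
  al <- gpa_align(generate_landmarks(sp))
  expect_equal(mean_class_shape_distance(al), 0, tolerance = 1e-10)
})

test_that("variance ratio matches a hand computation and is scale invariant", {
  x <- matrix(c(0, 0.1, 1, 1.1), ncol = 1)
  labels <- c("a", "a", "b", "b")
  # hand: class means .05/1.05, grand .55; B = 2*(.5^2)*2/3; W = 4*(.05^2)/3
  tr_b <- (2 * 0.5^2 + 2 * 0.5^2) / 3
  tr_w <- (4 * 0.05^2) / 3
  expect_equal(variance_ratio(x, labels), tr_b / tr_w, tolerance = 1e-12)
  expect_equal(variance_ratio(3 * x, labels), variance_ratio(x, labels),
               tolerance = 1e-12)
  expect_error(variance_ratio(matrix(c(0, 0, 1, 1), ncol = 1), labels),
               "no within-class variation")
  # identical class means: ratio 0
  x0 <- matrix(c(0, 1, 0, 1), ncol = 1)
  expect_equal(variance_ratio(x0, labels), 0)
})

test_that("between plus within variance traces equal the total covariance trace", {
  set.seed(8)
  x <- matrix(rnorm(60 * 5), 60, 5)
  labels <- sample(c("a", "b", "c"), 60, replace = TRUE)
  grand <- colMeans(x)
  n <- nrow(x)
  tr_b <- 0; tr_w <- 0
  for (cl in unique(labels)) {
    xi <- x[labels == cl, , drop = FALSE]
    mu <- colMeans(xi)
    tr_b <- tr_b + nrow(xi) * sum((mu - grand)^2)
    tr_w <- tr_w + sum(sweep(xi, 2, mu)^2)
  }
  total <- sum(diag(cov(x)))
  expect_equal((tr_b + tr_w) / (n - 1), total, tolerance = 1e-10)
  # and the package decomposition reproduces the ratio of those pieces
  expect_equal(variance_ratio(x, labels), tr_b / tr_w, tolerance = 1e-10)
})

test_that("class balance is normalized Shannon entropy", {
  expect_equal(class_balance(c(10, 10, 10)), 1, tolerance = 1e-12)
  expect_equal(class_balance(c(99, 1)), 0.0808, tolerance = 1e-3)
  expect_equal(class_balance(c(50, 25, 25)), 0.9464, tolerance = 1e-3)
  expect_error(class_balance(c(5)), "at least 2")
})

test_that("all property statistics are invariant to specimen order", {
  sp <- synthetic_spec(n_classes = 2, class_counts = 25, p = 8, delta = 0.1,
                       noise_sd = 0.04, seed = 9)
  al <- gpa_align(generate_landmarks(sp))
  set.seed(10)
  perm <- sample(50)
  expect_equal(class_r2(al$flat, al$labels),
               class_r2(al$flat[perm, ], al$labels[perm]), tolerance = 1e-10)
  expect_equal(variance_ratio(al$flat, al$labels),
               variance_ratio(al$flat[perm, ], al$labels[perm]),
               tolerance = 1e-10)
  expect_equal(mean_class_cov_distance(al$flat, al$labels),
               mean_class_cov_distance(al$flat[perm, ], al$labels[perm]),
               tolerance = 1e-10)
  expect_equal(mean_class_shape_distance(al, al$labels),
               mean_class_shape_distance(al, al$labels))
})

test_that("separation statistics increase monotonically with generating class separation", {
  deltas <- c(0.02, 0.05, 0.1, 0.2, 0.35)
  rho <- function(v) cor(v, seq_along(v), method = "spearman")
  for (seed in 1:3) {
    stats <- t(sapply(deltas, function(d) {
      sp <- synthetic_spec(n_classes = 2, class_counts = 60, p = 8,
                           delta = d, noise_sd = 0.03, seed = seed)
      al <- gpa_align(generate_landmarks(sp))
      c(r2 = class_r2(al$flat, al$labels),
        shape = mean_class_shape_distance(al),
        vr = variance_ratio(al$flat, al$labels))
    }))
    expect_equal(rho(stats[, "r2"]), 1)
    expect_equal(rho(stats[, "shape"]), 1)
    expect_equal(rho(stats[, "vr"]), 1)
  }
})

test_that("meta-regression recovers a noise-free linear model exactly", {
  set.seed(11)
  prop <- runif(20)
  task <- rep(c(0, 1), 10)
  perf <- 80 - 20 * task + 50 * prop
  # summary.lm warns about the essentially perfect fit; that is the point
  res <- suppressWarnings(meta_regression(perf, prop, task, unit = 0.1))
  expect_equal(res$variable_effect_per_unit, 5, tolerance = 1e-8)
  expect_equal(res$task_effect, -20, tolerance = 1e-8)
  expect_equal(res$r2, 1, tolerance = 1e-8)
  # effect scales linearly with the unit convention
  res2 <- suppressWarnings(meta_regression(perf, prop, task, unit = 0.01))
  expect_equal(res$variable_effect_per_unit,
               10 * res2$variable_effect_per_unit, tolerance = 1e-10)
  # character task flags work
  res3 <- suppressWarnings(
    meta_regression(perf, prop, ifelse(task == 1, "multi", "binary")))
  expect_equal(res3$task_effect, -20, tolerance = 1e-8)
})

test_that("meta-regression on an unrelated property finds no effect", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    task <- rep(c(0, 1), n / 2)
    prop <- runif(n)
    perf <- 75 - 10 * task + rnorm(n, sd = 5)
    res <- meta_regression(perf, prop, task, unit = 0.1)
    coef_se <- summary(res$fit)$coefficients["prop", "Std. Error"] * 0.1
    expect_lt(abs(res$variable_effect_per_unit), 3 * coef_se)
  }
  expect_error(meta_regression(1:10, runif(10), rep(0, 10)),
               "both binary and multi")
})

test_that("dataset_properties assembles all statistics with the right task flag", {
  sp <- synthetic_spec(n_classes = 3, class_counts = c(30, 20, 10), p = 8,
                       delta = 0.12, noise_sd = 0.03, seed = 12)
  al <- gpa_align(generate_landmarks(sp))
  props <- dataset_properties(al)
  expect_identical(props$task, "multi")
  expect_identical(props$sample_size, 60L)
  expect_equal(props$class_balance, class_balance(c(30, 20, 10)),
               tolerance = 1e-12)
  expect_true(props$class_r2 > 0 && props$class_r2 < 1)
})
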