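test_that("IQR filter removes a gross outlier at the hand-computed fence and nothing else", {
  # 29 inliers at graded small distances from the template, one specimen
  # an order of magnitude further out
  base <- oracle_center_unit(random_shape(8, seed = 6))
  set.seed(99)
  coords <- array(NA_real_, c(30, 8, 2))
  for (i in 1:29) {
    d <- matrix(rnorm(16), 8, 2)
    d <- d / sqrt(sum(d^2))
    coords[i, , ] <- base + 0.01 * (0.5 + 0.5 * i / 29) * d
  }
  d <- matrix(rnorm(16), 8, 2)
  coords[30, , ] <- base + 0.2 * d / sqrt(sum(d^2))
  al <- gpa_align(landmark_dataset(coords, labels = rep("a", 30)))
  flt <- procrustes_iqr_filter(al)
  expect_identical(flt$removed, 30L)
  qs <- quantile(flt$distances, c(.25, .75), names = FALSE)
  expect_equal(flt$threshold, qs[2] + 1.5 * (qs[2] - qs[1]), tolerance = 1e-12)
  expect_identical(which(flt$distances > flt$threshold + 1e-12), 30L)
})

test_that("IQR filter keeps identical copies and everything under an infinite multiplier", {
  base <- oracle_center_unit(random_shape(6, seed = 1))
  coords <- array(NA_real_, c(8, 6, 2))
  for (i in 1:8) coords[i, , ] <- base
  al <- gpa_align(landmark_dataset(coords, labels = rep("a", 8)))
  expect_length(procrustes_iqr_filter(al)$removed, 0)

  sp <- synthetic_spec(n_classes = 2, class_counts = 10, p = 6,
                       delta = 0.3, noise_sd = 0.1, seed = 2)
  al2 <- gpa_align(generate_landmarks(sp))
  expect_length(procrustes_iqr_filter(al2, multiplier = Inf)$removed, 0)
})

test_that("IQR filter never empties a class when labels are supplied", {
  sp <- synthetic_spec(n_classes = 1, class_counts = 12, p = 8,
                       delta = 0, noise_sd = 0.005, nuisance = FALSE, seed = 3)
  ds <- generate_landmarks(sp)
  set.seed(7)
  ds$coords[12, , ] <- ds$coords[12, , ] + 0.5 * matrix(rnorm(16), 8, 2)
  ds$labels[12] <- "rare"
  al <- gpa_align(ds)
  expect_warning(flt <- procrustes_iqr_filter(al, labels = ds$labels), "rare")
  expect_length(flt$removed, 0)
})

test_that("anomaly-score correlation matches hand-computed Pearson r and rejects constants", {
  expect_equal(anomaly_score_correlation(1:5, 1:5 * 2), 1)
  expect_equal(anomaly_score_correlation(1:5, -(1:5)), -1)
  # hand: deviations (-1,0,1) and (-7/3,-1/3,8/3); r = 2.5 / sqrt(2 * 38/6)
  expect_equal(anomaly_score_correlation(c(1, 2, 3), c(2, 4, 7)),
               2.5 / sqrt(1 * 114 / 18), tolerance = 1e-12)
  expect_error(anomaly_score_correlation(rep(1, 5), 1:5), "constant")
  expect_error(anomaly_score_correlation(1:4, 1:5), "equal length")
})

test_that("isolation-forest scores flag planted outliers and are deterministic", {
  set.seed(10)
  x <- rbind(matrix(rnorm(60 * 3, sd = 0.5), 60, 3),
             matrix(rnorm(3 * 3, mean = 6), 3, 3))
  s1 <- isolation_scores(x, n_trees = 50, seed = 4)
  s2 <- isolation_scores(x, n_trees = 50, seed = 4)
  expect_identical(s1, s2)
  expect_gt(min(s1[61:63]), max(s1[1:60]))
})

test_that("two-stage split reproduces the documented allocations", {
  # single class of 101: 15 test, 13 validation, 73 training
  part <- stratified_split(rep("a", 101), seed = 1)
  expect_length(part$test_idx, 15)
  expect_length(part$validation_idx, 13)
  expect_length(part$train_idx, 73)
  # two classes of 50: per class 8 test, round(.15*42)=6 validation
  part2 <- stratified_split(rep(c("a", "b"), each = 50), seed = 2)
  lab <- rep(c("a", "b"), each = 50)
  for (cl in c("a", "b")) {
    expect_length(intersect(part2$test_idx, which(lab == cl)), 8)
    expect_length(intersect(part2$validation_idx, which(lab == cl)), 6)
    expect_length(intersect(part2$train_idx, which(lab == cl)), 36)
  }
})

test_that("splits are seed-deterministic, disjoint, exhaustive, and class-proportionate", {
  set.seed(42)
  for (rep in 1:5) {
    n_classes <- sample(2:4, 1)
    labels <- sample(letters[1:n_classes], 40 + rep * 13, replace = TRUE)
    while (min(table(labels)) < 3)
      labels <- sample(letters[1:n_classes], 40 + rep * 13, replace = TRUE)
    p1 <- stratified_split(labels, seed = rep)
    p2 <- stratified_split(labels, seed = rep)
    expect_identical(p1, p2)
    all_idx <- c(p1$train_idx, p1$validation_idx, p1$test_idx)
    expect_identical(sort(all_idx), seq_along(labels))
    expect_length(intersect(p1$train_idx, p1$test_idx), 0)
    expect_length(intersect(p1$validation_idx, p1$test_idx), 0)
    # every class appears in every partition
    for (part in list(p1$train_idx, p1$validation_idx, p1$test_idx))
      expect_setequal(unique(labels[part]), unique(labels))
  }
  expect_error(stratified_split(c("a", "a", "b")), "fewer than 3")
})

test_that("direct scheme realizes exact 70/15/15 fractions for balanced classes divisible by 20", {
  labels <- rep(c("a", "b"), each = 40)
  part <- stratified_split(labels, seed = 5, scheme = "direct")
  expect_length(part$test_idx, 12)
  expect_length(part$validation_idx, 12)
  expect_length(part$train_idx, 56)
})

test_that("PCA retains the data rank at a 0.95 threshold and everything at 1.0", {
  set.seed(1)
  basis <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  x <- matrix(rnorm(60 * 2), 60, 2) %*% t(basis)  # rank-2 in 10D
  model <- pca_fit(x, 0.95)
  expect_identical(model$n_retained, 2L)
  x2 <- matrix(rnorm(15 * 6), 15, 6)
  expect_identical(pca_fit(x2, 1.0)$n_retained, 6L)
  x3 <- matrix(rnorm(4 * 9), 4, 9)
  expect_identical(pca_fit(x3, 1.0)$n_retained, 3L)  # min(n-1, d)
})

test_that("PCA of isotropic 5D noise spreads variance evenly across 5 components", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(4000 * 5), 4000, 5)
    model <- pca_fit(x, 0.95)
    expect_identical(model$n_retained, 5L)
    expect_true(all(abs(model$explained_variance_ratio - 0.2) < 0.02))
  }
})

test_that("PCA projection is consistent, centered, and orthonormal", {
  set.seed(9)
  x <- matrix(rnorm(50 * 8), 50, 8) %*% diag(c(4, 3, 2, 1, .5, .3, .2, .1))
  model <- pca_fit(x, 0.99)
  expect_equal(pca_project(model, x), model$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(pca_project(model, colMeans(x)))), 1e-8)
  expect_lt(max(abs(colMeans(model$scores))), 1e-8)
  cc <- crossprod(model$scores) / (nrow(x) - 1)
  offdiag <- abs(cc[upper.tri(cc)])
  expect_lt(max(offdiag), 1e-6 * max(diag(cc)))
  rtr <- crossprod(model$rotation)
  expect_equal(rtr, diag(model$n_retained), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_project(model, matrix(0, 2, 5)), "mismatch")
})

test_that("held-out reconstruction error is non-increasing in the number of components", {
  set.seed(12)
  x <- matrix(rnorm(40 * 6), 40, 6) %*% diag(c(3, 2.5, 2, 1.5, 1, .5))
  hold <- matrix(rnorm(10 * 6), 10, 6) %*% diag(c(3, 2.5, 2, 1.5, 1, .5))
  model <- pca_fit(x, 1.0)
  errs <- sapply(seq_len(model$n_retained), function(m) {
    rot <- model$rotation[, 1:m, drop = FALSE]
    rec <- sweep(sweep(hold, 2, model$center) %*% rot %*% t(rot),
                 2, -model$center)
    sum((hold - rec)^2)
  })
  expect_true(all(diff(errs) <= 1e-8))
})
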