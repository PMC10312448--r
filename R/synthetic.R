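# template shapes, centered and scaled to unit centroid size
regular_polygon <- function(p) {
  ang <- 2 * pi * (seq_len(p) - 1) / p
  center_scale(cbind(cos(ang), sin(ang)))
}

spiral_shape <- function(p) {
  t <- seq(0, 3 * pi, length.out = p)
  center_scale(cbind(cos(t), sin(t), t / (3 * pi)))
}

# uniform random rotation matrix in SO(k)
random_rotation <- function(k) {
  if (k == 2L) {
    th <- runif(1, 0, 2 * pi)
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  } else {
    qr_ <- qr(matrix(rnorm(k * k), k, k))
    q <- qr.Q(qr_)
    d <- diag(qr.R(qr_))
    q <- q %*% diag(sign(d), k)
    if (det(q) < 0) q[, 1L] <- -q[, 1L]
    q
  }
}

#' Specify a synthetic landmark dataset
#'
#' Defines the generating conditions for [generate_landmarks()]:
#' class-structured mean shapes on a common template, per-class Gaussian
#' landmark noise with controllable heterogeneity, and optional nuisance
#' rotation/translation/scaling per specimen.
#'
#' Class mean shapes are built by adding a centered random displacement
#' field (drawn from a geometry seed stream separate from the specimen
#' noise stream, so the class geometry is reproducible independently of
#' the noise) to the previous class mean and rescaling the displacement
#' so consecutive means sit at Procrustes distance `delta` (verified
#' internally to 1e-6).
#'
#' @param n_classes Number of classes (>= 1).
#' @param class_counts Specimens per class (recycled to `n_classes`).
#' @param p,k Landmarks and dimensions; the default template is a regular
#'   polygon for `k = 2` and a spiral for `k = 3`.
#' @param base_shape Optional `p x k` template (centered/unit-size
#'   internally).
#' @param delta Target Procrustes distance between consecutive class mean
#'   shapes (>= 0; must be realizable, i.e. `< sqrt(2)`).
#' @param noise_sd Within-class landmark noise standard deviation (shape
#'   units, i.e. relative to unit centroid size).
#' @param cov_heterogeneity Per-class multipliers on the noise standard
#'   deviation (recycled).
#' @param nuisance Logical: apply random rotation, translation (uniform in
#'   a cube of width 10), and log-uniform scaling in `[0.5, 2]` to each
#'   specimen.
#' @param seed Integer master seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 2L, class_counts = 50L, p = 10L,
                           k = 2L, base_shape = NULL, delta = 0.1,
                           noise_sd = 0.02, cov_heterogeneity = 1,
                           nuisance = TRUE, seed = 1L) {
  stopifnot(n_classes >= 1L, p >= 3L, k %in% c(2L, 3L),
            delta >= 0, noise_sd >= 0)
  if (delta >= sqrt(2))
    stop("delta = ", delta, " is not realizable on the shape sphere ",
         "(chord limit sqrt(2))", call. = FALSE)
  class_counts <- rep_len(as.integer(class_counts), n_classes)
  if (any(class_counts < 1L)) stop("class counts must be positive", call. = FALSE)
  cov_heterogeneity <- rep_len(cov_heterogeneity, n_classes)
  if (is.null(base_shape))
    base_shape <- if (k == 2L) regular_polygon(p) else spiral_shape(p)
  base_shape <- center_scale(as.matrix(base_shape))
  stopifnot(nrow(base_shape) == p, ncol(base_shape) == k)
  structure(
    list(n_classes = n_classes, class_counts = class_counts, p = p, k = k,
         base_shape = base_shape, delta = delta, noise_sd = noise_sd,
         cov_heterogeneity = cov_heterogeneity, nuisance = isTRUE(nuisance),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# move `delta` away from `from` along a centered displacement field
shift_mean_shape <- function(from, disp, delta) {
  if (delta == 0) return(from)
  f <- function(c) procrustes_distance(from, from + c * disp) - delta
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  c_star <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
  target <- center_scale(from + c_star * disp)
  stopifnot(abs(procrustes_distance(from, target) - delta) < 1e-6)
  target
}

#' Generate a synthetic landmark dataset
#'
#' Draws specimens as class mean shape plus i.i.d. Gaussian landmark
#' noise, then optionally applies nuisance rotation, translation, and
#' scaling. Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [landmark_dataset()]; the generating class means are
#'   attached as attribute `"class_means"`.
#' @export
generate_landmarks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$p; k <- spec$k
  # class geometry stream
  set.seed(derive_seed(spec$seed, "geometry"))
  means <- vector("list", spec$n_classes)
  means[[1L]] <- spec$base_shape
  if (spec$n_classes > 1L) {
    for (j in 2:spec$n_classes) {
      disp <- matrix(rnorm(p * k), p, k)
      disp <- sweep(disp, 2L, colMeans(disp))
      means[[j]] <- shift_mean_shape(means[[j - 1L]], disp, spec$delta)
    }
  }
  n <- sum(spec$class_counts)
  coords <- array(NA_real_, c(n, p, k))
  labels <- character(n)
  # specimen noise stream
  set.seed(derive_seed(spec$seed, "noise"))
  i <- 0L
  for (j in seq_len(spec$n_classes)) {
    sdj <- spec$noise_sd * spec$cov_heterogeneity[j]
    for (r in seq_len(spec$class_counts[j])) {
      i <- i + 1L
      coords[i, , ] <- means[[j]] + matrix(rnorm(p * k, sd = sdj), p, k)
      labels[i] <- sprintf("class_%02d", j)
    }
  }
  # nuisance stream
  if (spec$nuisance) {
    set.seed(derive_seed(spec$seed, "nuisance"))
    for (i in seq_len(n)) {
      rot <- random_rotation(k)
      scale <- exp(runif(1, log(0.5), log(2)))
      shift <- runif(k, -5, 5)
      coords[i, , ] <- sweep(scale * coords[i, , ] %*% rot, 2L, -shift)
    }
  }
  out <- landmark_dataset(coords, labels)
  attr(out, "class_means") <- means
  attr(out, "spec") <- spec
  out
}

#' Generate a grid of synthetic datasets with a truth table
#'
#' Cartesian product of class-separation values, class-count settings,
#' and seeds; every generated dataset is paired with a truth-table row
#' recording its generating parameters for downstream parameter-recovery
#' studies.
#'
#' @param base_spec A [synthetic_spec()] providing all other settings.
#' @param delta_grid Numeric vector of class separations.
#' @param balance_grid List of class-count vectors.
#' @param seeds Integer vector of seeds.
#' @return List with `datasets` (list of [landmark_dataset()]) and
#'   `truth` (data frame, one row per dataset: `id`, `delta`, `counts`,
#'   `seed`, `noise_sd`).
#' @export
generate_grid <- function(base_spec, delta_grid, balance_grid, seeds) {
  stopifnot(inherits(base_spec, "synthetic_spec"),
            length(delta_grid) >= 1L, length(balance_grid) >= 1L,
            length(seeds) >= 1L)
  if (!is.list(balance_grid)) balance_grid <- list(balance_grid)
  datasets <- list()
  truth <- NULL
  id <- 0L
  for (delta in delta_grid) for (counts in balance_grid) for (seed in seeds) {
    id <- id + 1L
    sp <- base_spec
    sp$delta <- delta
    sp$class_counts <- rep_len(as.integer(counts), sp$n_classes)
    sp$seed <- as.integer(seed)
    datasets[[id]] <- generate_landmarks(sp)
    truth <- rbind(truth, data.frame(
      id = sprintf("dataset_%03d", id), delta = delta,
      counts = paste(sp$class_counts, collapse = "+"),
      seed = seed, noise_sd = sp$noise_sd))
  }
  names(datasets) <- truth$id
  list(datasets = datasets, truth = truth)
}
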