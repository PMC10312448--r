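# independent re-implementations used as oracles; deliberately not calling
# into the package's own alignment code

# center a configuration and scale it to unit centroid size
oracle_center_unit <- function(m) {
  m <- sweep(m, 2L, colMeans(m))
  m / sqrt(sum(m^2))
}

# brute-force partial Procrustes distance for 2D shapes: evaluate the
# squared distance over a fine grid of rotation angles applied to the
# centered, unit-size second configuration
oracle_grid_distance <- function(a, b, step = 1e-4) {
  a <- oracle_center_unit(as.matrix(a))
  b <- oracle_center_unit(as.matrix(b))
  theta <- seq(0, 2 * pi, by = step)
  c1 <- sum(a * b)
  c2 <- sum(a[, 2] * b[, 1] - a[, 1] * b[, 2])
  d2 <- 2 - 2 * (c1 * cos(theta) + c2 * sin(theta))
  sqrt(max(min(d2), 0))
}

# random planar shape
random_shape <- function(p, k = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(p * k), p, k)
}

# apply a random rotation/translation/scaling to a configuration
nuisance_transform <- function(m) {
  k <- ncol(m)
  if (k == 2L) {
    th <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  } else {
    q <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
    if (det(q) < 0) q[, 1L] <- -q[, 1L]
    rot <- q
  }
  scale <- exp(runif(1, log(0.5), log(2)))
  shift <- matrix(runif(k, -5, 5), nrow(m), k, byrow = TRUE)
  scale * m %*% rot + shift
}

# two well-separated Gaussian blobs as a flat feature task
make_blobs <- function(n_per = 40L, d = 5L, sep = 10, seed = 1L, classes = 2L) {
  set.seed(seed)
  x <- NULL; y <- character(0)
  for (cl in seq_len(classes)) {
    mu <- rep(0, d); mu[cl] <- sep * (cl - 1)  # class cl sits on axis cl
    x <- rbind(x, matrix(rnorm(n_per * d), n_per, d) +
                 matrix(mu, n_per, d, byrow = TRUE))
    y <- c(y, rep(sprintf("c%d", cl), n_per))
  }
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, y = y)
}

fast_scheme <- list(type = "bootstrap", B = 10L)
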