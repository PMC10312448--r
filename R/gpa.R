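#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid — the standard size measure removed by Procrustes scaling.
#'
#' @param config Numeric `p x k` matrix of landmark coordinates.
#' @return A strictly positive scalar.
#' @examples
#' sq <- rbind(c(-.5, -.5), c(.5, -.5), c(.5, .5), c(-.5, .5))
#' centroid_size(sq)  # sqrt(2)
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (!all(is.finite(config))) stop("non-finite coordinates", call. = FALSE)
  cs <- sqrt(sum(sweep(config, 2L, colMeans(config))^2))
  if (cs < 1e-12)
    stop("degenerate configuration: all landmarks coincide", call. = FALSE)
  cs
}

# center and scale one configuration to unit centroid size
center_scale <- function(config, id = NULL) {
  config <- as.matrix(config)
  ctr <- sweep(config, 2L, colMeans(config))
  cs <- sqrt(sum(ctr^2))
  if (cs < 1e-12)
    stop("degenerate configuration",
         if (!is.null(id)) paste0(" for specimen '", id, "'") else "",
         ": all landmarks coincide", call. = FALSE)
  ctr / cs
}

# optimal proper rotation R (det +1) minimizing ||B %*% R - A||_F.
# Kabsch solution with the sign correction applied to the smallest
# singular vector so reflections are never introduced.
optimal_rotation <- function(a, b) {
  m <- crossprod(b, a)
  sv <- svd(m)
  k <- ncol(m)
  s <- sign(det(sv$u) * det(sv$v))
  if (s == 0) s <- 1
  d <- c(rep(1, k - 1L), s)
  sv$u %*% (d * t(sv$v))
}

#' Generalized Procrustes alignment
#'
#' Iteratively superimposes all configurations of a [landmark_dataset()]
#' into a common shape space: each specimen is translated to a zero
#' centroid, scaled to unit centroid size (partial-Procrustes convention;
#' size is fixed thereafter), and rotated by a proper rotation onto the
#' current consensus. The consensus is the arithmetic mean of the aligned
#' configurations and is updated until the total Procrustes sum of squares
#' decreases by less than `tol`.
#'
#' @param dataset A [landmark_dataset()].
#' @param tol Convergence tolerance on the decrease of the summed squared
#'   distance to the consensus. Default `1e-10`.
#' @param max_iter Maximum number of consensus updates. On hitting the cap
#'   the result is returned with `converged = FALSE` and a warning.
#' @param tangent_project If `TRUE`, additionally projects the flattened
#'   coordinates orthogonally to the consensus direction (formal tangent
#'   projection). Off by default: aligned Procrustes coordinates are used
#'   directly as the Euclidean tangent-space approximation.
#'
#' @return An object of class `aligned_shapes`: list with `coords`
#'   (`n x p x k` aligned array), `centroid_sizes`, `consensus` (`p x k`
#'   mean shape), `flat` (`n x (p*k)` row-major flattening, columns
#'   `x1,y1[,z1],x2,...`), `converged`, `n_iterations`, `ss_trace` (the
#'   per-iteration objective, non-increasing), plus carried-through
#'   `ids` and `labels`.
#' @seealso [procrustes_distance()], [mean_shape()]
#' @export
gpa_align <- function(dataset, tol = 1e-10, max_iter = 100L,
                      tangent_project = FALSE) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  dm <- dim(dataset$coords)
  n <- dm[1L]; p <- dm[2L]; k <- dm[3L]

  raw_cs <- numeric(n)
  coords <- array(NA_real_, c(n, p, k))
  for (i in seq_len(n)) {
    cfg <- as.matrix(dataset$coords[i, , ])
    ctr <- sweep(cfg, 2L, colMeans(cfg))
    cs <- sqrt(sum(ctr^2))
    if (cs < 1e-12)
      stop("degenerate configuration for specimen '", dataset$ids[i],
           "': all landmarks coincide", call. = FALSE)
    raw_cs[i] <- cs
    coords[i, , ] <- ctr / cs
  }

  consensus <- apply(coords, c(2L, 3L), mean)
  ss_trace <- numeric(0)
  prev_ss <- Inf
  iter <- 0L
  converged <- TRUE
  if (n > 1L) {
    converged <- FALSE
    while (iter < max_iter) {
      iter <- iter + 1L
      for (i in seq_len(n))
        coords[i, , ] <- coords[i, , ] %*% optimal_rotation(consensus, coords[i, , ])
      consensus <- apply(coords, c(2L, 3L), mean)
      ss <- sum(sweep(coords, c(2L, 3L), consensus)^2)
      ss_trace <- c(ss_trace, ss)
      if (prev_ss - ss < tol) { converged <- TRUE; break }
      prev_ss <- ss
    }
    if (!converged)
      warning("GPA did not converge in ", max_iter, " iterations")
  }

  # canonical orientation: rotate the whole solution so the consensus lies
  # along its principal axes, with a deterministic proper-rotation sign
  # rule. This makes the output invariant to nuisance rotations of the
  # input specimens, not merely invariant up to a global rotation.
  if (n > 1L) {
    rot <- svd(consensus)$v
    if (det(rot) < 0) rot[, k] <- -rot[, k]
    cons_r <- consensus %*% rot
    for (j in seq_len(k - 1L)) {
      imax <- which.max(abs(cons_r[, j]))
      if (cons_r[imax, j] < 0) {
        flip <- diag(k); flip[j, j] <- -1; flip[k, k] <- -1
        rot <- rot %*% flip
        cons_r <- consensus %*% rot
      }
    }
    consensus <- cons_r
    for (i in seq_len(n)) coords[i, , ] <- coords[i, , ] %*% rot
  }

  flat <- t(apply(coords, 1L, function(m) as.vector(t(m))))
  if (n == 1L) flat <- matrix(flat, nrow = 1L)
  colnames(flat) <- flat_names(p, k)
  rownames(flat) <- dataset$ids
  if (tangent_project) {
    cvec <- as.vector(t(consensus))
    cvec <- cvec / sqrt(sum(cvec^2))
    flat <- flat - tcrossprod(flat %*% cvec, cvec)
  }
  dimnames(coords) <- list(dataset$ids, dataset$landmark_names, NULL)

  structure(
    list(coords = coords, centroid_sizes = raw_cs, consensus = consensus,
         flat = flat, converged = converged, n_iterations = iter,
         ss_trace = ss_trace, ids = dataset$ids, labels = dataset$labels),
    class = "aligned_shapes"
  )
}

#' @export
print.aligned_shapes <- function(x, ...) {
  dm <- dim(x$coords)
  cat(sprintf("aligned_shapes: %d specimens, %d landmarks, %dD; %s in %d iteration(s)\n",
              dm[1L], dm[2L], dm[3L],
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' The Euclidean norm of the difference between two landmark
#' configurations after centering, scaling to unit centroid size, and
#' optimal proper rotation of `b` onto `a` (partial Procrustes distance).
#' Symmetric in its arguments.
#'
#' @param a,b Numeric `p x k` coordinate matrices with matching dimensions.
#' @return Non-negative scalar; 0 iff `a` and `b` have identical shape.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop("configurations must share the same p and k", call. = FALSE)
  a2 <- center_scale(a)
  b2 <- center_scale(b)
  r <- optimal_rotation(a2, b2)
  sqrt(sum((b2 %*% r - a2)^2))
}

#' Mean shape of a subset of aligned specimens
#'
#' @param aligned An `aligned_shapes` object from [gpa_align()].
#' @param subset Integer (or logical) index of specimens; defaults to all.
#' @return A `p x k` coordinate matrix: the arithmetic mean of the
#'   selected aligned configurations.
#' @export
mean_shape <- function(aligned, subset = seq_len(dim(aligned$coords)[1L])) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  if (is.logical(subset)) subset <- which(subset)
  if (length(subset) == 0L) stop("empty subset", call. = FALSE)
  apply(aligned$coords[subset, , , drop = FALSE], c(2L, 3L), mean)
}
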