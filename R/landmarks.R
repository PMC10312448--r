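#' Construct a landmark dataset
#'
#' Bundles raw specimen landmark configurations with their class labels.
#' A configuration is a set of `p` homologous anatomical points in `k`
#' dimensions (`k` = 2 or 3); the dataset holds an `n x p x k` array of
#' coordinates in arbitrary units, one slice per specimen.
#'
#' @param coords Numeric array of dimension `n x p x k` with `p >= 3` and
#'   `k` in `{2, 3}`. All values must be finite.
#' @param labels Vector of class labels, length `n`. Stored as character.
#' @param ids Optional specimen identifiers, length `n`; defaults to
#'   `"spec0001"`, `"spec0002"`, ...
#' @param landmark_names Optional character vector of length `p`.
#'
#' @return An object of class `landmark_dataset`: a list with elements
#'   `ids`, `labels`, `coords`, `landmark_names`.
#' @examples
#' coords <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
#' ld <- landmark_dataset(coords, labels = rep(c("a", "b"), c(3, 2)))
#' ld
#' @export
landmark_dataset <- function(coords, labels, ids = NULL, landmark_names = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L)
    stop("`coords` must be an n x p x k array", call. = FALSE)
  dm <- dim(coords)
  n <- dm[1L]; p <- dm[2L]; k <- dm[3L]
  if (n < 1L) stop("at least one specimen is required", call. = FALSE)
  if (p < 3L) stop("at least 3 landmarks are required, got ", p, call. = FALSE)
  if (!k %in% c(2L, 3L)) stop("`k` must be 2 or 3, got ", k, call. = FALSE)
  if (!all(is.finite(coords)))
    stop("non-finite coordinates are not allowed", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("length(labels) must equal the number of specimens (", n, ")", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("spec%04d", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("length(ids) must equal n", call. = FALSE)
  if (anyDuplicated(ids)) stop("specimen ids must be unique", call. = FALSE)
  if (!is.null(landmark_names) && length(landmark_names) != p)
    stop("length(landmark_names) must equal p", call. = FALSE)
  dimnames(coords) <- list(ids, landmark_names, NULL)
  structure(
    list(ids = ids, labels = labels, coords = coords,
         landmark_names = landmark_names),
    class = "landmark_dataset"
  )
}

#' @export
print.landmark_dataset <- function(x, ...) {
  dm <- dim(x$coords)
  cat(sprintf("landmark_dataset: %d specimens, %d landmarks, %dD\n",
              dm[1L], dm[2L], dm[3L]))
  tab <- table(x$labels)
  cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.landmark_dataset <- function(x) dim(x$coords)

# subset specimens, keeping ids/labels in sync
subset_landmarks <- function(dataset, idx) {
  landmark_dataset(dataset$coords[idx, , , drop = FALSE],
                   labels = dataset$labels[idx],
                   ids = dataset$ids[idx],
                   landmark_names = dataset$landmark_names)
}

# flat variable names: row-major by landmark then dimension (x1,y1[,z1],x2,...)
flat_names <- function(p, k) {
  axes <- c("x", "y", "z")[seq_len(k)]
  paste0(rep(axes, times = p), rep(seq_len(p), each = k))
}
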