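#' Read a TPS landmark file
#'
#' Parses the de facto landmark interchange format: records of
#' `LM=p` (2D) or `LM3=p` (3D) followed by `p` coordinate lines, an
#' `ID=` line, and optional `SCALE=` (applied multiplicatively) and
#' `IMAGE=` lines. `CURVES=`/`POINTS=` blocks are skipped with a
#' warning. Class labels are joined from a sidecar CSV with columns
#' `id,label`.
#'
#' @param path TPS file path.
#' @param labels_path Optional CSV path (`id,label`); if missing, all
#'   specimens get label `"unlabelled"`.
#' @return A [landmark_dataset()].
#' @export
read_tps <- function(path, labels_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  configs <- list(); ids <- character(0); dims <- integer(0)
  i <- 1L; warned_curves <- FALSE
  while (i <= length(lines)) {
    ln <- lines[i]
    if (ln == "") { i <- i + 1L; next }
    m <- regmatches(ln, regexec("^LM(3?)\\s*=\\s*([0-9]+)$", ln,
                                ignore.case = TRUE))[[1L]]
    if (!length(m))
      stop("parse error at line ", i, ": expected LM=/LM3= record, got '",
           ln, "'", call. = FALSE)
    k <- if (m[2L] == "3") 3L else 2L
    p <- as.integer(m[3L])
    if (i + p > length(lines))
      stop("parse error at line ", i, ": truncated record", call. = FALSE)
    coord_lines <- lines[(i + 1L):(i + p)]
    vals <- lapply(seq_along(coord_lines), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(coord_lines[j], "\\s+")[[1L]]))
      if (length(v) != k || anyNA(v))
        stop("parse error at line ", i + j, ": expected ", k,
             " numeric coordinates", call. = FALSE)
      v
    })
    cfg <- do.call(rbind, vals)
    i <- i + p + 1L
    id <- NULL; scale <- 1
    while (i <= length(lines) && !grepl("^LM", lines[i], ignore.case = TRUE)) {
      ln <- lines[i]
      if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", ln, ignore.case = TRUE))
      } else if (grepl("^(CURVES|POINTS)\\s*=", ln, ignore.case = TRUE)) {
        if (!warned_curves) {
          warning("CURVES/POINTS blocks are skipped")
          warned_curves <- TRUE
        }
      } else if (grepl("^IMAGE\\s*=", ln, ignore.case = TRUE) || ln == "") {
        # ignored
      } else if (grepl("^[-0-9.]", ln)) {
        # curve points: skip silently once warned
      }
      i <- i + 1L
    }
    if (is.null(id))
      stop("parse error: record ending before line ", i,
           " is missing an ID= line", call. = FALSE)
    configs[[length(configs) + 1L]] <- cfg * scale
    ids <- c(ids, id)
    dims <- rbind(dims, c(p, k))
  }
  if (!length(configs)) stop("no landmark records found in ", path, call. = FALSE)
  if (nrow(unique(dims)) > 1L)
    stop("inconsistent landmark counts/dimensions across records: ",
         paste(apply(unique(dims), 1L, paste, collapse = "x"), collapse = " vs "),
         call. = FALSE)
  p <- dims[1L, 1L]; k <- dims[1L, 2L]
  coords <- array(NA_real_, c(length(configs), p, k))
  for (j in seq_along(configs)) coords[j, , ] <- configs[[j]]
  labels <- rep("unlabelled", length(ids))
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    if (!all(c("id", "label") %in% names(lab)))
      stop("labels CSV must have columns id,label", call. = FALSE)
    hit <- match(ids, lab$id)
    if (anyNA(hit))
      stop("missing labels for id(s): ",
           paste(ids[is.na(hit)], collapse = ", "), call. = FALSE)
    labels <- as.character(lab$label[hit])
  }
  landmark_dataset(coords, labels, ids = ids)
}

#' Write a TPS landmark file
#'
#' @param dataset A [landmark_dataset()].
#' @param path Output TPS path.
#' @param labels_path Optional path for a sidecar `id,label` CSV.
#' @return `path`, invisibly.
#' @export
write_tps <- function(dataset, path, labels_path = NULL) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  dm <- dim(dataset$coords)
  tag <- if (dm[3L] == 3L) "LM3" else "LM"
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(dm[1L])) {
    writeLines(sprintf("%s=%d", tag, dm[2L]), con)
    cfg <- dataset$coords[i, , ]
    writeLines(apply(cfg, 1L, function(r)
      paste(sprintf("%.12g", r), collapse = " ")), con)
    writeLines(sprintf("ID=%s", dataset$ids[i]), con)
  }
  if (!is.null(labels_path))
    utils::write.csv(data.frame(id = dataset$ids, label = dataset$labels),
                     labels_path, row.names = FALSE)
  invisible(path)
}

#' Read a wide CSV of landmarks or flat features
#'
#' Expects a header row with columns `id`, `class`, then either
#' coordinate-style columns `x1,y1[,z1],x2,...` (landmark mode, detected
#' from the header names) or arbitrary numeric feature columns (flat
#' mode, which bypasses Procrustes alignment).
#'
#' @param path CSV path.
#' @return A [landmark_dataset()] in landmark mode, or a list
#'   `list(features, labels, ids, mode = "flat")` in flat mode.
#' @export
read_wide_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "class") %in% names(df)))
    stop("wide CSV must start with columns id,class", call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  feat_names <- setdiff(names(df), c("id", "class"))
  feats <- df[feat_names]
  bad <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric data column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(feats)
  landmark_mode <- all(grepl("^[xyz][0-9]+$", feat_names))
  if (landmark_mode) {
    axes <- unique(sub("[0-9]+$", "", feat_names))
    k <- length(axes)
    p <- length(feat_names) / k
    expected <- flat_names(p, k)
    if (p != round(p) || !identical(sort(feat_names), sort(expected)))
      landmark_mode <- FALSE
  }
  if (landmark_mode) {
    x <- x[, expected, drop = FALSE]  # canonical x1,y1[,z1],x2,... order
    coords <- array(NA_real_, c(nrow(x), p, k))
    for (i in seq_len(nrow(x))) coords[i, , ] <- matrix(x[i, ], p, k, byrow = TRUE)
    landmark_dataset(coords, labels = df$class, ids = df$id)
  } else {
    rownames(x) <- df$id
    list(features = x, labels = as.character(df$class), ids = df$id,
         mode = "flat")
  }
}
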