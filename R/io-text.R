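#' Read a plain-text point cloud
#'
#' Parses `x y z [label]` lines, whitespace- or comma-delimited. With
#' `label_scheme = "raw"` the fourth column is kept untouched (instance ids);
#' with `"leaf_tip"` instance labels are collapsed to semantic
#' ground/stem/leaf immediately, matching the leaf-tip relabelling convention
#' where every leaf id joins a single leaf class.
#'
#' @param path file to read.
#' @param label_scheme `"raw"` or `"leaf_tip"`.
#' @param plant_id,day metadata attached to the returned cloud.
#' @return a `point_cloud`.
#' @export
read_points_txt <- function(path, label_scheme = c("raw", "leaf_tip"),
                            plant_id = NULL, day = 0L) {
  label_scheme <- match.arg(label_scheme)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("empty point cloud file: ", path)
  toks <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  nf <- lengths(toks)
  bad <- which(nf < 3L | nf > 4L)
  if (length(bad) > 0L)
    stop(sprintf("parse error at line %d of %s: expected 3 or 4 fields, got %d",
                 keep[bad[1L]], path, nf[bad[1L]]))
  if (!all(nf == nf[1L])) {
    mixed <- which(nf != nf[1L])[1L]
    stop(sprintf("parse error at line %d of %s: inconsistent field count",
                 keep[mixed], path))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))),
              ncol = nf[1L], byrow = TRUE)
  if (anyNA(m)) {
    bad_line <- keep[which(rowSums(is.na(m)) > 0L)[1L]]
    stop(sprintf("parse error at line %d of %s: non-numeric field",
                 bad_line, path))
  }
  labels <- NULL
  class_names <- NULL
  if (ncol(m) == 4L) {
    if (any(abs(m[, 4L] - round(m[, 4L])) > 0))
      stop("label column must be integer-valued in ", path)
    labels <- as.integer(round(m[, 4L]))
  }
  if (is.null(plant_id))
    plant_id <- tools::file_path_sans_ext(basename(path))
  cl <- point_cloud(m[, 1:3, drop = FALSE], labels, class_names,
                    plant_id, day, path)
  if (!is.null(labels) && label_scheme == "leaf_tip") cl <- relabel_semantic(cl)
  cl
}

#' Write a point cloud as plain text
#'
#' One `x y z [label]` line per point, space separated, preserving point
#' order.
#'
#' @param cloud a `point_cloud`.
#' @param path output file.
#' @export
write_points_txt <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  m <- cloud$coords
  if (!is.null(cloud$labels)) m <- cbind(m, cloud$labels)
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
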