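#' Labelled plant point cloud
#'
#' The universal sample unit: an N x 3 coordinate matrix with optional
#' per-point integer labels and plant metadata. Semantic clouds use the fixed
#' class order ground (0), stem (1), leaf (2); raw clouds may carry per-leaf
#' instance labels (ids >= 2).
#'
#' @param coords numeric N x 3 matrix of point coordinates (source units).
#' @param labels optional integer vector of length N, values in
#'   `[0, length(class_names))` when `class_names` is given.
#' @param class_names ordered character vector of semantic class names, or
#'   `NULL` for raw (instance-labelled or unlabelled) clouds.
#' @param plant_id plant identifier (string).
#' @param day integer day/growth-stage index.
#' @param source path or description of where the cloud came from.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(coords, labels = NULL, class_names = NULL,
                        plant_id = "plant", day = 0L, source = "") {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stop("coords must be a numeric N x 3 matrix")
  if (nrow(coords) < 1L) stop("point cloud must contain at least one point")
  if (!all(is.finite(coords))) stop("coords contain non-finite values")
  dimnames(coords) <- NULL
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(coords))
      stop("labels length must equal the number of points")
    if (anyNA(labels)) stop("labels contain missing values")
    if (any(labels < 0L)) stop("labels must be non-negative")
    if (!is.null(class_names) && any(labels >= length(class_names)))
      stop("labels exceed the number of classes")
  }
  structure(list(coords = coords, labels = labels, class_names = class_names,
                 plant_id = as.character(plant_id), day = as.integer(day),
                 source = source),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, plant '%s', day %d\n",
              nrow(x$coords), x$plant_id, x$day))
  if (is.null(x$labels)) {
    cat("  labels: absent\n")
  } else {
    tab <- table(x$labels)
    nm <- if (!is.null(x$class_names)) x$class_names[as.integer(names(tab)) + 1L]
          else names(tab)
    cat("  labels:", paste(sprintf("%s=%d", nm, tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Semantic class names used throughout the package
#' @export
semantic_classes <- function() c("ground", "stem", "leaf")

#' Collapse instance labels to semantic ground/stem/leaf labels
#'
#' Raw clouds label each leaf with its own instance id; for semantic
#' segmentation all leaves share one class. Under the default label map,
#' 0 = ground and 1 = stem are kept and every id >= 2 becomes leaf (2). The
#' map is configurable because the numeric coding of source datasets varies.
#'
#' @param cloud a `point_cloud` with raw labels.
#' @param label_map optional function mapping raw integer labels to semantic
#'   labels in `{0, 1, 2}`; the default implements the convention above.
#' @return a `point_cloud` with labels in `{0, 1, 2}` and
#'   `class_names = c("ground", "stem", "leaf")`; point order unchanged.
#' @export
relabel_semantic <- function(cloud, label_map = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$labels)) stop("cloud has no labels to relabel")
  raw <- cloud$labels
  if (any(raw < 0L)) stop("negative raw labels are not allowed")
  sem <- if (is.null(label_map)) pmin(raw, 2L) else as.integer(label_map(raw))
  if (any(sem < 0L | sem > 2L)) stop("label_map produced labels outside {0,1,2}")
  point_cloud(cloud$coords, sem, semantic_classes(),
              cloud$plant_id, cloud$day, cloud$source)
}

#' Bundle of point clouds with a plant-level train/test split
#'
#' @param clouds list of `point_cloud` objects.
#' @param split named character vector mapping every plant id to `"train"` or
#'   `"test"`; defaults to all-train.
#' @param provenance free-text description of the bundle's origin.
#' @return an object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(clouds, split = NULL, provenance = "") {
  stopifnot(is.list(clouds), length(clouds) >= 0L)
  for (cl in clouds) stopifnot(inherits(cl, "point_cloud"))
  ids <- unique(vapply(clouds, function(cl) cl$plant_id, ""))
  if (is.null(split)) split <- stats::setNames(rep("train", length(ids)), ids)
  split <- vapply(split, as.character, "")
  if (!all(ids %in% names(split)))
    stop("every plant id must appear in the split table")
  if (!all(split %in% c("train", "test")))
    stop("split values must be 'train' or 'test'")
  structure(list(clouds = clouds, split = split, provenance = provenance),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("<dataset_bundle> %d clouds, %d plants (%d train / %d test)\n",
              length(x$clouds), length(x$split),
              sum(x$split == "train"), sum(x$split == "test")))
  invisible(x)
}

#' @export
length.dataset_bundle <- function(x) length(x$clouds)

#' Partition a bundle by plant identity
#'
#' Splitting is always at the plant level: every cloud of a plant goes to the
#' same side, so repeated scans of one plant never leak across the split.
#'
#' @param bundle a `dataset_bundle`.
#' @param train_ids character vector of plant ids to place in the training set.
#' @return a list with `train` and `test` bundles.
#' @export
split_by_plant <- function(bundle, train_ids) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  train_ids <- as.character(train_ids)
  ids <- vapply(bundle$clouds, function(cl) cl$plant_id, "")
  unknown <- setdiff(train_ids, ids)
  if (length(unknown) > 0L)
    stop("unknown plant id(s) in train_ids: ", paste(unknown, collapse = ", "))
  in_train <- ids %in% train_ids
  mk <- function(cls, subset_name) {
    sid <- unique(vapply(cls, function(cl) cl$plant_id, ""))
    dataset_bundle(cls, stats::setNames(rep(subset_name, length(sid)), sid),
                   bundle$provenance)
  }
  list(train = mk(bundle$clouds[in_train], "train"),
       test  = mk(bundle$clouds[!in_train], "test"))
}
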