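# Adaptive voxelization. The grid resolution is tied to the cloud's longest
# bounding-box axis rather than to a fixed metric edge, so plants scanned at
# different growth stages (or in different units) occupy the grid at a
# comparable resolution — occupancy patterns are invariant to global scale.

#' Fit an adaptive voxel grid to a cloud
#'
#' Voxels are cubic; the edge length is the padded longest bounding-box
#' extent divided by `target_longest_axis_voxels`, and per-axis dimensions
#' cover the padded box. Scaling a cloud globally leaves the occupancy
#' pattern unchanged.
#'
#' @param cloud a `point_cloud`.
#' @param target_longest_axis_voxels number of voxels along the longest
#'   axis (>= 2); default 128.
#' @param pad padding added on every side of the bounding box, in source
#'   units.
#' @return a `grid_spec` with fields `origin`, `voxel_size` (scalar edge,
#'   replicated per axis) and `dims`.
#' @export
fit_grid <- function(cloud, target_longest_axis_voxels = 128L, pad = 0) {
  stopifnot(inherits(cloud, "point_cloud"), target_longest_axis_voxels >= 2L,
            pad >= 0)
  lo <- apply(cloud$coords, 2L, min) - pad
  hi <- apply(cloud$coords, 2L, max) + pad
  ext <- hi - lo
  longest <- max(ext)
  if (longest <= 0) stop("degenerate cloud: zero extent on every axis")
  edge <- longest / target_longest_axis_voxels
  dims <- pmax(1L, as.integer(ceiling(ext / edge - 1e-9)))
  structure(list(origin = lo, voxel_size = rep(edge, 3L), dims = dims),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> dims %s, voxel edge %.4g\n",
              paste(x$dims, collapse = "x"), x$voxel_size[1L]))
  invisible(x)
}

#' Assign points to voxels
#'
#' Cells are half-open `[lo, hi)`; a point landing exactly on the grid's max
#' corner is clamped into the last cell. The active-voxel list is
#' deduplicated and lexicographically sorted.
#'
#' @param cloud a `point_cloud`.
#' @param spec a `grid_spec` covering it (as produced by [fit_grid()]).
#' @return a `voxel_assignment` with fields `spec`, `point_to_voxel` (index
#'   into the active list), `active_coords` (M x 3, 0-based integer voxel
#'   coordinates) and `counts`.
#' @export
voxel_assign <- function(cloud, spec) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(spec, "grid_spec"))
  p <- cloud$coords
  ijk <- floor(sweep(sweep(p, 2L, spec$origin, "-"), 2L, spec$voxel_size, "/"))
  for (a in 1:3) {
    out <- ijk[, a] < 0 | ijk[, a] > spec$dims[a]
    if (any(out))
      stop("point outside the voxel grid on axis ", a,
           "; fit the grid to this cloud first")
    ijk[, a] <- pmin(ijk[, a], spec$dims[a] - 1L)  # max-corner clamp
  }
  storage.mode(ijk) <- "integer"
  key <- coord_key(ijk, spec$dims)
  act_key <- sort(unique(key))
  p2v <- match(key, act_key)
  active <- key_coord(act_key, spec$dims)
  structure(list(spec = spec, point_to_voxel = p2v, active_coords = active,
                 counts = tabulate(p2v, nbins = length(act_key))),
            class = "voxel_assignment")
}

# Bijective integer key for voxel coordinates (0-based), lexicographic in
# (x, y, z). Doubles hold the products exactly at any realistic resolution.
coord_key <- function(ijk, dims) {
  (as.numeric(ijk[, 1L]) * dims[2L] + ijk[, 2L]) * dims[3L] + ijk[, 3L]
}

key_coord <- function(key, dims) {
  z <- key %% dims[3L]
  xy <- (key - z) / dims[3L]
  y <- xy %% dims[2L]
  x <- (xy - y) / dims[2L]
  m <- cbind(x, y, z)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' @export
print.voxel_assignment <- function(x, ...) {
  cat(sprintf("<voxel_assignment> %d points in %d active voxels (dims %s)\n",
              length(x$point_to_voxel), nrow(x$active_coords),
              paste(x$spec$dims, collapse = "x")))
  invisible(x)
}

#' Per-voxel max-reduction of point features
#'
#' Row `m` of the result is the elementwise maximum over the features of the
#' points assigned to active voxel `m` — the symmetric (order-invariant)
#' reduction of the mini-PointNet convention. `reduce = "mean"` averages
#' instead.
#'
#' @param point_features numeric N x C matrix.
#' @param assignment a `voxel_assignment` for the same N points.
#' @param reduce `"max"` (default) or `"mean"`.
#' @return an M x C matrix.
#' @export
scatter_max <- function(point_features, assignment, reduce = c("max", "mean")) {
  reduce <- match.arg(reduce)
  point_features <- as.matrix(point_features)
  if (nrow(point_features) != length(assignment$point_to_voxel))
    stop("feature rows do not match the assignment")
  m <- nrow(assignment$active_coords)
  if (reduce == "max") {
    grouped_max(point_features, assignment$point_to_voxel, m)$max
  } else {
    rs <- rowsum(point_features, assignment$point_to_voxel, reorder = TRUE)
    unname(rs / assignment$counts)
  }
}

#' Broadcast voxel features back to points
#'
#' Row `i` of the result is the feature row of the voxel containing point
#' `i`.
#'
#' @param voxel_features numeric M x C matrix over active voxels.
#' @param assignment a `voxel_assignment`.
#' @return an N x C matrix.
#' @export
voxel_gather <- function(voxel_features, assignment) {
  voxel_features <- as.matrix(voxel_features)
  if (nrow(voxel_features) != nrow(assignment$active_coords))
    stop("feature rows do not match the assignment's active voxels")
  voxel_features[assignment$point_to_voxel, , drop = FALSE]
}

#' Coarsen a voxel assignment by an integer factor
#'
#' Voxel coordinates are floor-divided by `factor` and the point mapping is
#' recomputed consistently; `coarsen(coarsen(a, 2), 2)` equals
#' `coarsen(a, 4)`.
#'
#' @param assignment a `voxel_assignment`.
#' @param factor integer >= 2.
#' @return a coarser `voxel_assignment`.
#' @export
coarsen <- function(assignment, factor) {
  stopifnot(inherits(assignment, "voxel_assignment"), factor >= 2L)
  factor <- as.integer(factor)
  spec <- assignment$spec
  new_dims <- pmax(1L, as.integer(ceiling(spec$dims / factor)))
  new_spec <- structure(list(origin = spec$origin,
                             voxel_size = spec$voxel_size * factor,
                             dims = new_dims),
                        class = "grid_spec")
  fine <- assignment$active_coords %/% factor
  key <- coord_key(fine, new_dims)
  act_key <- sort(unique(key))
  fine_to_coarse <- match(key, act_key)
  p2v <- fine_to_coarse[assignment$point_to_voxel]
  structure(list(spec = new_spec, point_to_voxel = p2v,
                 active_coords = key_coord(act_key, new_dims),
                 counts = tabulate(p2v, nbins = length(act_key))),
            class = "voxel_assignment")
}
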